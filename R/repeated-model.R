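#' Repeated-measures mixed model with AR(1) within-pig correlation
#'
#' Fits the Gaussian model `y = X beta + pig + e`, where `pig` is a random
#' intercept per pig (variance `sigma2_pig`) and the residuals of a pig are
#' correlated across its timepoints with a stationary first-order
#' autoregressive structure (`cor(e_s, e_t) = rho^|s - t|` on the timepoint
#' order, variance `sigma2_e`). Variance parameters are estimated by
#' maximizing the restricted likelihood (REML) of the profiled covariance
#' `V = sigma2_e (phi J + R(rho))`, fixed effects by generalized least
#' squares at the optimum. Each fixed-effect term gets a sequential
#' (whitened) F statistic with containment denominator degrees of freedom
#' `n_obs - n_pigs - rank(X) + 1`.
#'
#' Unevenly spaced sampling days are handled as the study's model statement
#' implies: the correlation decays per step of timepoint *order*, not per
#' day.
#'
#' @param data data frame holding the response, covariates, and the pig and
#'   time columns.
#' @param formula fixed-effects formula, e.g. `y ~ treatment + timepoint`.
#' @param pig name of the pig (cluster) column.
#' @param time name of the timepoint column; its sorted unique values define
#'   the AR(1) step order.
#' @param correlation `"ar1"` or `"none"` (fixes `rho = 0`).
#' @param random_pig `FALSE` fixes `sigma2_pig = 0`; together with
#'   `correlation = "none"` the fit reduces exactly to ordinary least
#'   squares.
#' @param start optional named vector `c(phi = , rho = )` of starting values
#'   (`phi = sigma2_pig / sigma2_e`), e.g. to warm-start bootstrap refits.
#' @param optim_control control list passed to [stats::optim()] (L-BFGS-B).
#' @return a `wb_rmfit` object: fixed-effect `coefficients` and `vcov`,
#'   variance estimates `sigma2_pig`, `sigma2_e`, `rho`, a per-term ANOVA
#'   tibble (`term`, `df`, `statistic`, `p_value`), convergence flags, and
#'   the profiled REML criterion.
#' @export
fit_repeated_model <- function(data, formula, pig = "pig", time = "timepoint",
                               correlation = c("ar1", "none"),
                               random_pig = TRUE, start = NULL,
                               optim_control = list(factr = 1e9)) {
  correlation <- match.arg(correlation)
  data <- as.data.frame(data)
  if (!pig %in% names(data)) abort(paste0("No pig column '", pig, "'."))
  if (!time %in% names(data)) abort(paste0("No time column '", time, "'."))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  used <- as.integer(rownames(mf))
  if (is.null(used) || anyNA(used)) used <- seq_len(nrow(mf))
  pig_f <- factor(data[[pig]][used])
  tvals <- data[[time]][used]
  tlev <- if (is.factor(tvals)) levels(droplevels(tvals)) else sort(unique(tvals))
  tidx <- match(as.character(tvals), as.character(tlev))
  n <- length(y)
  p <- qr(X)$rank
  if (p < ncol(X)) abort("Rank-deficient fixed-effects design.")
  term_labels <- attr(terms(mf), "term.labels")
  assign <- attr(X, "assign")

  # pigs grouped by timepoint pattern so the 4x4 work is shared
  ord <- order(pig_f, tidx)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  pig_f <- pig_f[ord]; tidx <- tidx[ord]
  pigs <- split(seq_len(n), pig_f)
  patterns <- vapply(pigs, function(ix) paste(tidx[ix], collapse = ","), "")
  pat_groups <- split(seq_along(pigs), patterns)
  n_pigs <- length(pigs)

  est_phi <- random_pig
  est_rho <- correlation == "ar1"

  # per-pattern blocks precomputed once: the response and design rows of all
  # pigs sharing a timepoint pattern, reshaped so one Cholesky whitens them
  # all in a single triangular solve
  np <- ncol(X)
  blocks <- lapply(pat_groups, function(g) {
    tt <- tidx[pigs[[g[1]]]]
    rows <- unlist(pigs[g], use.names = FALSE)
    m <- length(g); t_len <- length(tt)
    list(tt = tt, rows = rows, m = m, t_len = t_len,
         lag = abs(outer(tt, tt, "-")),
         Yb = matrix(y[rows], t_len, m),
         Xb = matrix(X[rows, , drop = FALSE], t_len, m * np))
  })

  # profiled negative REML criterion (up to an additive constant):
  # (n - p) log RSS0 + log|V0| + log|X' V0^-1 X|
  suff <- function(phi, rho) {
    XtX <- matrix(0, np, np)
    Xty <- numeric(np)
    yty <- 0
    logdet <- 0
    for (b in blocks) {
      if (b$t_len == 1L) {
        v <- phi + 1
        logdet <- logdet + log(v) * b$m
        Ywh <- b$Yb / sqrt(v)
        Xwh <- b$Xb / sqrt(v)
        dim(Xwh) <- c(b$m, np)
      } else {
        L <- chol(phi + rho^b$lag)
        logdet <- logdet + 2 * sum(log(diag(L))) * b$m
        Ywh <- backsolve(L, b$Yb, transpose = TRUE)
        Xwh <- backsolve(L, b$Xb, transpose = TRUE)
        dim(Xwh) <- c(b$t_len * b$m, np)
      }
      yty <- yty + sum(Ywh^2)
      XtX <- XtX + crossprod(Xwh)
      Xty <- Xty + drop(crossprod(Xwh, c(Ywh)))
    }
    list(XtX = XtX, Xty = Xty, yty = yty, logdet = logdet)
  }
  crit <- function(phi, rho) {
    tryCatch({
      s <- suff(phi, rho)
      R <- chol(s$XtX)
      beta <- backsolve(R, backsolve(R, s$Xty, transpose = TRUE))
      rss <- s$yty - 2 * sum(beta * s$Xty) + sum(beta * (s$XtX %*% beta))
      if (rss <= 0) rss <- 1e-300
      (n - p) * log(rss) + s$logdet + 2 * sum(log(diag(R)))
    }, error = function(e) 1e10)
  }
  # full whitened data, needed only once at the optimum
  whiten <- function(phi, rho) {
    yw <- numeric(n)
    Xw <- matrix(0, n, np)
    for (b in blocks) {
      L <- chol(phi + rho^b$lag)
      yw[b$rows] <- as.vector(backsolve(L, b$Yb, transpose = TRUE))
      Xw[b$rows, ] <- matrix(backsolve(L, b$Xb, transpose = TRUE),
                             b$t_len * b$m, np)
    }
    list(yw = yw, Xw = Xw)
  }

  const_y <- sd(y) < 1e-12 * (abs(mean(y)) + 1)
  theta_to_par <- function(th) {
    i <- 1
    phi <- 0; rho <- 0
    if (est_phi) { phi <- exp(th[i]); i <- i + 1 }
    if (est_rho) rho <- tanh(th[i])
    c(phi = phi, rho = rho)
  }
  converged <- TRUE
  if (const_y || (!est_phi && !est_rho)) {
    par <- c(phi = 0, rho = 0)
    opt_value <- crit(0, 0)
  } else {
    obj <- function(th) {
      pr <- theta_to_par(th)
      crit(pr["phi"], pr["rho"])
    }
    phi0 <- max(min(start[["phi"]] %||% 0.5, 100), 1e-4)
    rho0 <- max(min(start[["rho"]] %||% 0.3, 0.95), -0.95)
    th0 <- c(if (est_phi) log(phi0), if (est_rho) atanh(rho0))
    lower <- c(if (est_phi) -15, if (est_rho) -3.8)
    upper <- c(if (est_phi) 8, if (est_rho) 3.8)
    opt <- if (length(th0) == 1) {
      o <- stats::optimize(function(t1) obj(t1), c(lower, upper))
      list(par = o$minimum, value = o$objective, convergence = 0)
    } else {
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = optim_control)
    }
    converged <- opt$convergence == 0
    if (!converged) {
      abort(paste0("REML optimization failed to converge: code ",
                   opt$convergence, " ", opt$message %||% ""))
    }
    par <- theta_to_par(opt$par)
    opt_value <- opt$value
  }
  phi <- unname(par["phi"]); rho <- unname(par["rho"])
  # a pig-variance estimate of ~0 (lower bound) is a common, benign outcome;
  # only a correlation pinned near +-1 or an exploding variance ratio gets a
  # warning
  boundary <- (est_rho && abs(rho) > 0.99) || (est_phi && phi > 2500)
  if (boundary) warn("Variance/correlation estimate at parameter boundary.")

  w <- whiten(phi, rho)
  qrw <- qr(w$Xw)
  beta <- qr.coef(qrw, w$yw)
  rss <- sum(qr.resid(qrw, w$yw)^2)
  sigma2_e <- if (const_y) 0 else rss / (n - p)
  XtXi <- chol2inv(qr.R(qrw))
  dimnames(XtXi) <- list(colnames(X), colnames(X))

  ddf <- if (random_pig) n - n_pigs - p + 1L else n - p
  if (ddf < 1) ddf <- 1L
  # sequential (type-I) F per fixed-effect term on the whitened data
  terms_tbl <- NULL
  if (length(term_labels) > 0) {
    ss <- numeric(length(term_labels))
    prev_ss <- if (0 %in% assign) {
      f0 <- qr.fitted(qr(w$Xw[, assign == 0, drop = FALSE]), w$yw)
      sum(f0^2)
    } else 0
    for (k in seq_along(term_labels)) {
      cols <- which(assign <= k)
      fk <- qr.fitted(qr(w$Xw[, cols, drop = FALSE]), w$yw)
      ss[k] <- sum(fk^2) - prev_ss
      prev_ss <- sum(fk^2)
    }
    q <- vapply(seq_along(term_labels), function(k) sum(assign == k), 0L)
    Fstat <- if (const_y) rep(0, length(ss)) else (ss / q) / sigma2_e
    Fstat[Fstat < 0] <- 0
    pval <- ifelse(Fstat == 0, 1, pf(Fstat, q, ddf, lower.tail = FALSE))
    terms_tbl <- tibble(term = term_labels, df = q, ddf = as.integer(ddf),
                        statistic = Fstat, p_value = pval)
  }
  structure(list(
    formula = formula,
    coefficients = beta,
    vcov = sigma2_e * XtXi,
    sigma2_pig = phi * sigma2_e,
    sigma2_e = sigma2_e,
    rho = if (est_rho || correlation == "ar1") rho else 0,
    terms = terms_tbl,
    n = n, n_pigs = n_pigs, rank = p, ddf = ddf,
    converged = converged, boundary = boundary,
    reml_criterion = opt_value,
    crit_fn = crit
  ), class = "wb_rmfit")
}

#' @export
print.wb_rmfit <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures fit: %d obs, %d pigs | sigma2_pig = %.4g, sigma2_e = %.4g, rho = %.3f\n",
    x$n, x$n_pigs, x$sigma2_pig, x$sigma2_e, x$rho))
  if (!is.null(x$terms)) print(as.data.frame(x$terms), row.names = FALSE)
  invisible(x)
}

#' Per-taxon differential-abundance tests
#'
#' Fits the repeated-measures model `value ~ treatment + timepoint` (pig
#' random intercept, AR(1) residuals) to each taxon's normalized counts at
#' each requested taxonomic level, and flags taxa whose treatment term has
#' `p < alpha`. No multiple-testing correction is applied (the protocol uses
#' the raw 0.05 cut-off). Taxa that are all-zero in any treatment x
#' timepoint cell are skipped and counted.
#'
#' @param norm_table a CSS-normalized `otu_tbl`.
#' @param alpha significance cut-off on the treatment p-value.
#' @param ranks character vector of levels to test; `"otu"` tests the
#'   unaggregated rows.
#' @return tibble `rank`, `taxon_id`, `statistic`, `p_value`, `significant`;
#'   attribute `n_skipped` counts degenerate taxa.
#' @export
per_otu_tests <- function(norm_table, alpha = 0.05,
                          ranks = c("phylum", "class", "order", "family",
                                    "genus", "otu")) {
  stopifnot(is_otu_table(norm_table))
  if (!is_normalized(norm_table)) {
    warn("per_otu_tests expects a CSS-normalized table.")
  }
  md <- sample_meta(norm_table)
  cell <- interaction(md$treatment, md$timepoint, drop = TRUE)
  n_skipped <- 0L
  res <- purrr::map_dfr(ranks, function(rk) {
    tab <- if (rk == "otu") norm_table else aggregate_taxonomy(norm_table, rk)
    m <- otu_counts(tab)
    purrr::map_dfr(rownames(m), function(tx) {
      yv <- m[tx, ]
      if (any(tapply(yv, cell, function(v) all(v == 0)))) {
        n_skipped <<- n_skipped + 1L
        return(NULL)
      }
      d <- tibble(y = yv, treatment = md$treatment,
                  timepoint = md$timepoint, pig = md$pig)
      fit <- fit_repeated_model(d, y ~ treatment + timepoint)
      tr <- fit$terms[fit$terms$term == "treatment", ]
      tibble(rank = rk, taxon_id = tx,
             statistic = tr$statistic, p_value = tr$p_value)
    })
  })
  if (n_skipped > 0) {
    inform(sprintf("Skipped %d degenerate taxa (all-zero in a cell).", n_skipped))
  }
  res$significant <- res$p_value < alpha
  attr(res, "n_skipped") <- n_skipped
  res
}
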