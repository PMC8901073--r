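#' Construct an OTU table
#'
#' The pipeline's central object: a tibble with one row per taxon, the six
#' lineage rank columns (`domain` .. `genus`), and one numeric count column
#' per sample, with the sample metadata attached as an attribute. Raw tables
#' hold non-negative integer counts; CSS-normalized tables (see
#' [css_normalize()]) hold non-negative reals and carry their per-sample
#' scaling factors.
#'
#' @param counts numeric matrix (taxa x samples) with column names matching
#'   `metadata$sample`, or a data frame of sample columns.
#' @param lineages tibble/data.frame with columns `taxon_id` and the six ranks
#'   returned by [wb_ranks()]; missing ranks must already carry explicit
#'   `"uncultured"`/`"unclassified"` labels.
#' @param metadata sample metadata; coerced via [sample_metadata()].
#' @param normalized logical; `TRUE` for CSS-normalized values.
#' @param scaling_factors,scale_constant CSS bookkeeping (normalized tables).
#' @param rank the taxonomic rank of the rows (`"otu"` for unaggregated
#'   tables, or one of [wb_ranks()] after [aggregate_taxonomy()]).
#' @return an `otu_tbl` (a tibble subclass).
#' @export
otu_table <- function(counts, lineages, metadata, normalized = FALSE,
                      scaling_factors = NULL, scale_constant = NULL,
                      rank = "otu") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  metadata <- sample_metadata(metadata)
  lineages <- as_tibble(lineages)
  stopifnot("taxon_id" %in% names(lineages))
  keep_ranks <- intersect(wb_ranks(), names(lineages))
  if (anyDuplicated(lineages$taxon_id)) {
    abort("Duplicated taxon_id in lineages.")
  }
  if (nrow(lineages) != nrow(counts)) {
    abort("lineages and counts disagree on the number of taxa.")
  }
  if (is.null(colnames(counts))) abort("counts must have sample column names.")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Negative count at taxon row %d, sample '%s'.",
                  bad[1, 1], colnames(counts)[bad[1, 2]]))
  }
  if (!normalized) {
    nonint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(nonint) > 0) {
      abort(sprintf("Non-integer count at taxon row %d, sample '%s'.",
                    nonint[1, 1], colnames(counts)[nonint[1, 2]]))
    }
  }
  missing_meta <- setdiff(colnames(counts), metadata$sample)
  if (length(missing_meta) > 0) {
    abort(paste0("No metadata for sample(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample), ]
  empty <- colnames(counts)[colSums(counts) == 0]
  if (length(empty) > 0) {
    abort(paste0("All-zero sample column(s): ", paste(empty, collapse = ", ")))
  }
  out <- bind_cols(
    lineages[, c("taxon_id", keep_ranks)],
    as_tibble(counts, .name_repair = "minimal")
  )
  structure(
    out,
    class = c("otu_tbl", class(tibble())),
    metadata = metadata,
    normalized = normalized,
    scaling_factors = scaling_factors,
    scale_constant = scale_constant,
    rank = rank
  )
}

#' @rdname otu_table
#' @param x an object.
#' @export
is_otu_table <- function(x) inherits(x, "otu_tbl")

#' Accessors for `otu_tbl` objects
#'
#' `otu_counts()` returns the numeric taxa-by-sample matrix (rownames =
#' taxon ids), `otu_lineages()` the lineage tibble, `sample_meta()` the
#' attached sample metadata, `otu_rank()` the row rank, and
#' `is_normalized()` whether values are CSS-normalized.
#'
#' @param x an `otu_tbl`.
#' @name otu-accessors
NULL

#' @rdname otu-accessors
#' @export
otu_counts <- function(x) {
  stopifnot(is_otu_table(x))
  samples <- sample_meta(x)$sample
  m <- as.matrix(as.data.frame(x)[, samples, drop = FALSE])
  rownames(m) <- x$taxon_id
  m
}

#' @rdname otu-accessors
#' @export
otu_lineages <- function(x) {
  stopifnot(is_otu_table(x))
  keep <- intersect(c("taxon_id", wb_ranks()), names(x))
  as_tibble(as.data.frame(x)[, keep, drop = FALSE])
}

#' @rdname otu-accessors
#' @export
sample_meta <- function(x) attr(x, "metadata")

#' @rdname otu-accessors
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @rdname otu-accessors
#' @export
otu_rank <- function(x) attr(x, "rank") %||% "otu"

# Rebuild an otu_tbl with new counts but the same annotations/metadata.
replace_counts <- function(x, counts, normalized = is_normalized(x),
                           scaling_factors = attr(x, "scaling_factors"),
                           scale_constant = attr(x, "scale_constant"),
                           metadata = sample_meta(x), lineages = NULL,
                           rank = otu_rank(x)) {
  otu_table(counts, lineages %||% otu_lineages(x)[match(rownames(counts), x$taxon_id), ],
            metadata, normalized = normalized,
            scaling_factors = scaling_factors, scale_constant = scale_constant,
            rank = rank)
}

#' @export
print.otu_tbl <- function(x, ...) {
  md <- sample_meta(x)
  cat(sprintf(
    "# OTU table (%s): %d taxa x %d samples%s\n",
    otu_rank(x), nrow(x), nrow(md),
    if (is_normalized(x)) ", CSS-normalized" else ", raw counts"
  ))
  NextMethod()
  invisible(x)
}

#' Construct/validate sample metadata
#'
#' Expects columns `sample`, `pig`, `treatment`, `timepoint`; adds the derived
#' `period` factor (pre = T0/T1, post = T2/T3) and orders treatment levels
#' white < traditional < oil where applicable.
#'
#' @param df data frame of per-sample metadata.
#' @return tibble with factor `treatment`, `timepoint`, `period`.
#' @export
sample_metadata <- function(df) {
  df <- as_tibble(df)
  need <- c("sample", "pig", "treatment", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("Metadata lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample)) abort("Duplicated sample ids in metadata.")
  df$sample <- as.character(df$sample)
  df$pig <- as.character(df$pig)
  tr <- unique(as.character(df$treatment))
  lev <- c(intersect(wb_treatments(), tr), sort(setdiff(tr, wb_treatments())))
  df$treatment <- factor(as.character(df$treatment), levels = lev)
  df$timepoint <- factor(as.character(df$timepoint),
                         levels = sort(unique(as.character(df$timepoint))))
  df$period <- timepoint_period(df$timepoint)
  df
}

#' Read / write an OTU table as TSV
#'
#' The TSV layout is taxa rows by sample columns: `taxon_id`, the six lineage
#' columns, then one column per sample. A transposed table (samples as rows)
#' is detected by matching the first column against the metadata sample ids
#' and rejected rather than silently flipped.
#'
#' @param path TSV path.
#' @param metadata_path TSV with `sample`, `pig`, `treatment`, `timepoint`.
#' @param normalized logical; whether the values are CSS-normalized.
#' @return [read_otu_table()]: an `otu_tbl`; [write_otu_table()]: `path`,
#'   invisibly (the metadata is written alongside when `metadata_path` given).
#' @export
read_otu_table <- function(path, metadata_path, normalized = FALSE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  md <- read_sample_metadata(metadata_path)
  if (!"taxon_id" %in% names(tab)) {
    abort("OTU table lacks a 'taxon_id' column.")
  }
  if (mean(tab$taxon_id %in% md$sample) > 0.5) {
    abort("Table appears transposed (row ids match metadata samples); expected taxa rows x sample columns.")
  }
  keep_ranks <- intersect(wb_ranks(), names(tab))
  sample_cols <- setdiff(names(tab), c("taxon_id", keep_ranks))
  counts <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(counts) <- tab$taxon_id
  otu_table(counts, tab[, c("taxon_id", keep_ranks)], md,
            normalized = normalized)
}

#' @rdname read_otu_table
#' @param x an `otu_tbl`.
#' @export
write_otu_table <- function(x, path, metadata_path = NULL) {
  stopifnot(is_otu_table(x))
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  if (!is.null(metadata_path)) write_sample_metadata(sample_meta(x), metadata_path)
  invisible(path)
}

#' @rdname read_otu_table
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_otu_table
#' @param md a sample metadata tibble.
#' @export
write_sample_metadata <- function(md, path) {
  readr::write_tsv(md[, c("sample", "pig", "treatment", "timepoint")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write per-piglet growth tables as TSV
#'
#' Columns: `pig`, `group`, `bw_d1`, `bw_d26`, `bw_d58` (kg; `NA` after
#' death), `alive_pre`, `alive_post` (logical survival through each period).
#'
#' @param path TSV path.
#' @return a tibble of growth records.
#' @export
read_growth_table <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_growth(g)
}

#' @rdname read_growth_table
#' @param g a growth tibble.
#' @export
write_growth_table <- function(g, path) {
  readr::write_tsv(validate_growth(g), path, progress = FALSE)
  invisible(path)
}

validate_growth <- function(g) {
  g <- as_tibble(g)
  need <- c("pig", "group", "bw_d1", "bw_d26", "bw_d58", "alive_pre", "alive_post")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0) {
    abort(paste0("Growth table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bw <- as.matrix(g[, c("bw_d1", "bw_d26", "bw_d58")])
  if (any(bw <= 0, na.rm = TRUE)) abort("Body weights must be positive.")
  dec <- which(apply(bw, 1, function(r) any(diff(r[!is.na(r)]) < 0)))
  if (length(dec) > 0) {
    abort(sprintf("Body weight decreases for pig '%s'.", g$pig[dec[1]]))
  }
  if (any(!g$alive_pre & (!is.na(g$bw_d26) | !is.na(g$bw_d58)))) {
    abort("Pigs dead before weaning cannot have d26/d58 weights.")
  }
  g
}
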