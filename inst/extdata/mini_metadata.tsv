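sample	pig	treatment	timepoint
pigA_T0	pigA	white	T0
pigB_T0	pigB	oil	T0
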