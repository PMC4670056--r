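# Human sitting / walking / running from the trimodal SD_Heave histogram:
# sitting below the first interpeak minimum, then walking vs running at the
# second interpeak minimum of the same full-deployment histogram.
vocabulary: [sitting, moving, walking, running]
steps:
  - metric: sd_heave
    expected_k: 3
    gap: 1
    below: sitting
    above: moving
    bin_width: 0.02
  - metric: sd_heave
    expected_k: 3
    gap: 2
    below: walking
    above: running
    applies_to: moving
    bin_width: 0.02
    histogram_scope: all
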