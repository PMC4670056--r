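# Stepwise plan for a flying seabird: peel off flight first (most distinct),
# then split the remaining seconds into on-water / on-land by body pitch,
# with the land<->water transition rule enforced by averaging pitch between
# flight bouts.
vocabulary: [flight, nonflight, on_land, on_water]
steps:
  - metric: sd_heave
    expected_k: 2
    gap: 1
    below: nonflight
    above: flight
    bin_width: 0.02
  - metric: pitch
    expected_k: 2
    gap: 1
    below: on_water
    above: on_land
    applies_to: nonflight
    bin_width: 1
    bout_constraint:
      anchor: flight
      aggregate: mean
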