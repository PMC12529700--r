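{
  "comment": [
    "Ordered threshold configuration for the herd-classification tree.",
    "The published tree this emulates keeps its exact thresholds in an",
    "unavailable supplement; these defaults reproduce the taxonomy's",
    "behaviour on the synthetic population and are meant to be replaced",
    "when calibrating against real data. The fallback discriminator for",
    "herds empty at all three census months (trading vs fattening vs",
    "unclassified) is likewise a best guess: short-stay throughput means",
    "trading, inflow ending in on-site slaughter means fattening."
  ],
  "adult_age_days": 730,
  "min_calvings": 1,
  "dairy_adult_female_frac": 0.5,
  "mixed_min_frac": 0.3,
  "store_young_frac": 0.6,
  "trading_max_stay_days": 60,
  "trading_min_moves": 4,
  "fattening_min_inflow": 3,
  "beef_purity_bp": 0.95,
  "weanling_sale_age": 330,
  "youngstock_sale_age": 730,
  "male_calf_rearing_frac": 0.2
}
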