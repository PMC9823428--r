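- component: vegetables
  direction: adequacy
  reference_amount: 400.0
  max_points: 15.0
- component: fruits
  direction: adequacy
  reference_amount: 250.0
  max_points: 15.0
- component: grains
  direction: adequacy
  reference_amount: 300.0
  max_points: 10.0
- component: dairy
  direction: adequacy
  reference_amount: 250.0
  max_points: 10.0
- component: fish
  direction: adequacy
  reference_amount: 30.0
  max_points: 10.0
- component: beverages
  direction: adequacy
  reference_amount: 1500.0
  max_points: 10.0
- component: meat
  direction: moderation
  reference_amount: 85.0
  max_points: 10.0
  zero_point_multiple: 2.0
- component: eggs
  direction: moderation
  reference_amount: 30.0
  max_points: 10.0
  zero_point_multiple: 2.0
- component: spreadable_fats
  direction: moderation
  reference_amount: 30.0
  max_points: 10.0
  zero_point_multiple: 2.0
- component: alcohol
  direction: moderation
  reference_amount: 10.0
  max_points: 10.0
  zero_point_multiple: 2.0
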