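frequency_recode:
  never/rarely: 0.0
  1-2 times per week: 0.066
  3-6 times per week: 0.214
  1-2 times per day: 0.643
  3-4 times per day: 1.0
  '>5 times per day': 2.5
composition:
  item:
  - soup
  - salad_greens
  - rice
  - pasta
  - bread
  - cheese
  - meat
  - fish
  - legumes
  - potato
  - fruit
  - vegetables_cooked
  - yogurt
  - eggs
  water_fraction:
  - 0.92
  - 0.93
  - 0.68
  - 0.62
  - 0.36
  - 0.37
  - 0.6
  - 0.7
  - 0.7
  - 0.77
  - 0.86
  - 0.93
  - 0.85
  - 0.75
  serving_size:
  - 250.0
  - 150.0
  - 150.0
  - 180.0
  - 60.0
  - 30.0
  - 150.0
  - 150.0
  - 200.0
  - 200.0
  - 150.0
  - 150.0
  - 200.0
  - 100.0
beverage_servings:
  beverage:
  - juices_soda
  - coffee_milk
  - milkshake_granita
  - tea
  - alcohol
  serving_ml:
  - 330.0
  - 150.0
  - 250.0
  - 250.0
  - 330.0
  water_fraction:
  - 0.9
  - 0.95
  - 0.8
  - 0.99
  - 0.92
urine_loss_map:
- 800.0
- 1100.0
- 1400.0
- 1700.0
- 2000.0
fecal_loss_map:
- 50.0
- 100.0
- 150.0
- 250.0
- 400.0
sweat_rest_map:
- 300.0
- 377.7777778
- 455.5555556
- 533.3333333
- 611.1111111
- 688.8888889
- 766.6666667
- 844.4444444
- 922.2222222
- 1000.0
sweat_exercise_rates:
  vigorous: 1000.0
  moderate: 600.0
  walking: 300.0
sweat_scale_multipliers:
- 0.2
- 0.4
- 0.6
- 0.8
- 1.0
- 1.2
- 1.4
- 1.6
- 1.8
- 2.0
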