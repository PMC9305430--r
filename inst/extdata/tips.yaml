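# Nutrition tip pack. Tips are keyed by food category id; the synthetic
# catalog cycles six category archetypes (1 = produce, 2 = dairy, 3 = meat,
# 4 = snacks/sweets, 5 = staples, 6 = drinks; archetype =
# ((category_id - 1) mod 6) + 1). The entries below cover the first cycle;
# unmapped categories fall back to the generic tip.
fallback: tip_generic_balance
categories:
  "1":
    - tip_fill_half_plate_veg
    - tip_frozen_veg_counts
  "2":
    - tip_lower_fat_dairy
    - tip_lower_salt_cheese
  "3":
    - tip_lean_cuts
    - tip_legumes_instead_of_meat
  "4":
    - tip_swap_sweet_snacks
    - tip_portion_sweets
  "5":
    - tip_wholegrain_swap
  "6":
    - tip_water_over_soft_drinks
    - tip_unsweetened_drinks
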