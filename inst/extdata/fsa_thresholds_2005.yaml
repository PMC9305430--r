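# UK FSA nutrient profiling model, 2005 band table (per 100 g).
# Band semantics: value <= upper_bound -> points of the first matching band
# (lower-exclusive, upper-inclusive). Bands must be listed in ascending order.
# Fiber bands use the AOAC column, as in the Nutri-Score framework.
version: fsa-2005-aoac
components:
  energy:
    unit: kJ/100g
    kind: negative
    bands:
      - {upper_bound: 335, points: 0}
      - {upper_bound: 670, points: 1}
      - {upper_bound: 1005, points: 2}
      - {upper_bound: 1340, points: 3}
      - {upper_bound: 1675, points: 4}
      - {upper_bound: 2010, points: 5}
      - {upper_bound: 2345, points: 6}
      - {upper_bound: 2680, points: 7}
      - {upper_bound: 3015, points: 8}
      - {upper_bound: 3350, points: 9}
      - {upper_bound: .inf, points: 10}
  sugars:
    unit: g/100g
    kind: negative
    bands:
      - {upper_bound: 4.5, points: 0}
      - {upper_bound: 9.0, points: 1}
      - {upper_bound: 13.5, points: 2}
      - {upper_bound: 18.0, points: 3}
      - {upper_bound: 22.5, points: 4}
      - {upper_bound: 27.0, points: 5}
      - {upper_bound: 31.0, points: 6}
      - {upper_bound: 36.0, points: 7}
      - {upper_bound: 40.0, points: 8}
      - {upper_bound: 45.0, points: 9}
      - {upper_bound: .inf, points: 10}
  saturated_fat:
    unit: g/100g
    kind: negative
    bands:
      - {upper_bound: 1, points: 0}
      - {upper_bound: 2, points: 1}
      - {upper_bound: 3, points: 2}
      - {upper_bound: 4, points: 3}
      - {upper_bound: 5, points: 4}
      - {upper_bound: 6, points: 5}
      - {upper_bound: 7, points: 6}
      - {upper_bound: 8, points: 7}
      - {upper_bound: 9, points: 8}
      - {upper_bound: 10, points: 9}
      - {upper_bound: .inf, points: 10}
  sodium:
    unit: mg/100g
    kind: negative
    bands:
      - {upper_bound: 90, points: 0}
      - {upper_bound: 180, points: 1}
      - {upper_bound: 270, points: 2}
      - {upper_bound: 360, points: 3}
      - {upper_bound: 450, points: 4}
      - {upper_bound: 540, points: 5}
      - {upper_bound: 630, points: 6}
      - {upper_bound: 720, points: 7}
      - {upper_bound: 810, points: 8}
      - {upper_bound: 900, points: 9}
      - {upper_bound: .inf, points: 10}
  fvln:
    unit: percent
    kind: positive
    bands:
      - {upper_bound: 40, points: 0}
      - {upper_bound: 60, points: 1}
      - {upper_bound: 80, points: 2}
      - {upper_bound: .inf, points: 5}
  fiber:
    unit: g/100g
    kind: positive
    bands:
      - {upper_bound: 0.9, points: 0}
      - {upper_bound: 1.9, points: 1}
      - {upper_bound: 2.8, points: 2}
      - {upper_bound: 3.7, points: 3}
      - {upper_bound: 4.7, points: 4}
      - {upper_bound: .inf, points: 5}
  protein:
    unit: g/100g
    kind: positive
    bands:
      - {upper_bound: 1.6, points: 0}
      - {upper_bound: 3.2, points: 1}
      - {upper_bound: 4.8, points: 2}
      - {upper_bound: 6.4, points: 3}
      - {upper_bound: 8.0, points: 4}
      - {upper_bound: .inf, points: 5}
protein_cap:
  enabled: true
  negative_total_at_least: 11
  fvln_exemption_points: 5
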