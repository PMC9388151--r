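# 2017 Sante Publique France / UK FSA nutrient-profiling thresholds.
# Component points = number of thresholds strictly exceeded by the value
# (repeated thresholds encode point jumps, e.g. general fruit/veg 0-1-2-5).
# All values per 100 g (or 100 mL for beverages).
components:
  general:
    energy_kj:       [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
    saturated_fat_g: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
    sugars_g:        [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
    sodium_mg:       [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
    protein_g:       [1.6, 3.2, 4.8, 6.4, 8.0]
    fiber_g:         [0.9, 1.9, 2.8, 3.7, 4.7]
    fvno_percent:    [40, 60, 80, 80, 80]
  beverage:
    energy_kj:       [0, 30, 60, 90, 120, 150, 180, 210, 240, 270]
    sugars_g:        [0, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12, 13.5]
    # fruit/veg/nut/oil points for beverages step 0-2-4-10
    fvno_percent:    [40, 40, 60, 60, 80, 80, 80, 80, 80, 80]
  added_fat:
    # points on 100 * saturated fat / total fat
    satfat_ratio_percent: [10, 16, 22, 28, 34, 40, 46, 52, 58, 64]
protein_cap:
  # protein points are not counted when the negative sum reaches the
  # threshold unless fruit/veg/nut/oil points are at their food-type maximum;
  # cheese is exempt from the cap
  negative_threshold: 11
  fvno_full:
    general: 5
    cheese: 5
    added_fat: 5
    beverage: 10
  exempt_food_types: [cheese]
letters:
  # upper bound of total points for each class; E is everything above D
  food:
    A: -1
    B: 2
    C: 10
    D: 18
  beverage:
    # class A is reserved for plain water
    B: 1
    C: 5
    D: 9
scaled:
  # affine map of the -15..40 total to the 0..100 nutrition impact scale
  offset: 15
  range: 55
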