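# Default Chinese Preschooler Dietary Index (CPDI) scoring standard.
# Densities are amounts per 1000 kcal of energy intake; units per component.
# Age groups are completed years: "2-3" and "4-5".
name: CPDI
age_groups:
  - label: "2-3"
    energy_range: [1000, 1200]
  - label: "4-5"
    energy_range: [1200, 1400]
components:
  - component_id: vegetables
    display_name: Vegetables
    category: adequacy
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {recommended_density: 167}
      "4-5": {recommended_density: 179}
  - component_id: fruits
    display_name: Fruits
    category: adequacy
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {recommended_density: 83}
      "4-5": {recommended_density: 107}
  - component_id: dairy
    display_name: Dairy and dairy products
    category: adequacy
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {recommended_density: 417}
      "4-5": {recommended_density: 250}
  - component_id: soybeans
    display_name: Soybeans and its products
    category: adequacy
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {recommended_density: 4}
      "4-5": {recommended_density: 11}
  - component_id: aquatic
    display_name: Aquatic products
    category: adequacy
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {recommended_density: 12.5}
      "4-5": {recommended_density: 14}
  - component_id: cereals
    display_name: Cereals
    category: moderation
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {lower_density: 71, upper_density: 100, zero_above_density: 200}
      "4-5": {lower_density: 71, upper_density: 125, zero_above_density: 250}
  - component_id: eggs
    display_name: Eggs
    category: moderation
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {lower_density: 17, upper_density: 25, zero_above_density: 50}
      "4-5": {lower_density: 18, upper_density: 21, zero_above_density: 42}
  - component_id: red_meat_poultry
    display_name: Red meat and poultry
    category: moderation
    unit: g
    max_score: 10
    cutoffs:
      "2-3": {lower_density: 12.5, upper_density: 25, zero_above_density: 50}
      "4-5": {lower_density: 18, upper_density: 33, zero_above_density: 66}
  - component_id: vitamin_a
    display_name: Vitamin A
    category: moderation
    unit: ug_RAE
    max_score: 2.5
    cutoffs:
      "2-3": {lower_density: 258, upper_density: 700, zero_above_density: 1400}
      "4-5": {lower_density: 257, upper_density: 750, zero_above_density: 1500}
  - component_id: iron
    display_name: Iron
    category: moderation
    unit: mg
    max_score: 2.5
    cutoffs:
      "2-3": {lower_density: 7.5, upper_density: 25, zero_above_density: 50}
      "4-5": {lower_density: 7.1, upper_density: 25, zero_above_density: 50}
  - component_id: snacks
    display_name: High-sugar and high-fat snacks
    category: limitation
    unit: g
    max_score: 5
    cutoffs:
      "2-3": {limit_density: 100}
      "4-5": {limit_density: 100}
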