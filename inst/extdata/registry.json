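{
  "comment": "Default Health 2020 monitoring-framework registry. The indicator-to-target mapping is a synthetic reconstruction consistent with the published framework structure (19 indicators, 6 targets, 16 quantitative indicators, multi-target indicators 7/9/10/11, qualitative indicators 11/18/19, availability windows). Edit freely; the engine treats this file as data.",
  "targets": [
    {"target_id": 1, "name": "Reduce premature mortality in Europe", "is_quantitative": true},
    {"target_id": 2, "name": "Increase life expectancy in Europe", "is_quantitative": true},
    {"target_id": 3, "name": "Reduce inequities in health in Europe", "is_quantitative": true},
    {"target_id": 4, "name": "Enhance the well-being of the European population", "is_quantitative": true},
    {"target_id": 5, "name": "Universal coverage and the right to health", "is_quantitative": true},
    {"target_id": 6, "name": "National targets and goals set by Member States", "is_quantitative": false}
  ],
  "indicators": [
    {"indicator_id": 1, "name": "Premature mortality from major noncommunicable diseases", "is_quantitative": true, "direction": "lower_better", "target_ids": [1], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 2, "name": "Tobacco use prevalence", "is_quantitative": true, "direction": "lower_better", "target_ids": [1], "available_reference_years": [2015]},
    {"indicator_id": 3, "name": "Total alcohol consumption per capita", "is_quantitative": true, "direction": "lower_better", "target_ids": [1], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 4, "name": "Overweight prevalence among adults", "is_quantitative": true, "direction": "lower_better", "target_ids": [1], "available_reference_years": [2010, 2015]},
    {"indicator_id": 5, "name": "Measles and polio vaccination coverage", "is_quantitative": true, "direction": "higher_better", "target_ids": [1], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 6, "name": "Mortality from external causes", "is_quantitative": true, "direction": "lower_better", "target_ids": [1], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 7, "name": "Life expectancy at birth", "is_quantitative": true, "direction": "higher_better", "target_ids": [1, 2], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 8, "name": "Infant mortality rate", "is_quantitative": true, "direction": "lower_better", "target_ids": [3], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 9, "name": "Primary school enrolment", "is_quantitative": true, "direction": "higher_better", "target_ids": [3, 4], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 10, "name": "Unemployment rate", "is_quantitative": true, "direction": "lower_better", "target_ids": [3, 4], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 11, "name": "GINI coefficient (income distribution)", "is_quantitative": false, "direction": "lower_better", "target_ids": [3, 4], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 12, "name": "Life satisfaction", "is_quantitative": true, "direction": "higher_better", "target_ids": [4], "available_reference_years": [2010, 2015]},
    {"indicator_id": 13, "name": "Access to improved sanitation", "is_quantitative": true, "direction": "higher_better", "target_ids": [4], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 14, "name": "Social support", "is_quantitative": true, "direction": "higher_better", "target_ids": [4], "available_reference_years": [2015]},
    {"indicator_id": 15, "name": "Total health expenditure (% of GDP)", "is_quantitative": true, "direction": "higher_better", "target_ids": [5], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 16, "name": "Out-of-pocket share of health expenditure", "is_quantitative": true, "direction": "lower_better", "target_ids": [5], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 17, "name": "Skilled health personnel density", "is_quantitative": true, "direction": "higher_better", "target_ids": [5], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 18, "name": "Establishment of national Health 2020 targets", "is_quantitative": false, "direction": "higher_better", "target_ids": [6], "available_reference_years": [2005, 2010, 2015]},
    {"indicator_id": 19, "name": "Evidence of national policies aligned with Health 2020", "is_quantitative": false, "direction": "higher_better", "target_ids": [6], "available_reference_years": [2005, 2010, 2015]}
  ]
}
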