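# Base-case model parameters: every value is stored on its printed scale.
# `unit: percent` marks entries printed as percentages; they are divided by
# 100 when the file is loaded, so the file stays diff-able against the
# published parameter table.
schema_version: 1
parameters:
  carrier_prevalence: {base: 0.495, low: 0.452, high: 0.538, dist: beta, unit: percent}
  gene_prop:
    BRCA1:  {base: 0.276, low: 0.221, high: 0.332, dist: dirichlet}
    BRCA2:  {base: 0.290, low: 0.232, high: 0.348, dist: dirichlet}
    ATM:    {base: 0.121, low: 0.096, high: 0.145, dist: dirichlet}
    CHEK2:  {base: 0.145, low: 0.116, high: 0.174, dist: dirichlet}
    MSH6:   {base: 0.042, low: 0.034, high: 0.051, dist: dirichlet}
    PALB2:  {base: 0.091, low: 0.073, high: 0.109, dist: dirichlet}
    RAD51C: {base: 0.027, low: 0.022, high: 0.032, dist: dirichlet}
    TP53:   {base: 0.008, low: 0.006, high: 0.009, dist: dirichlet}
  fh_identification: {base: 0.174, low: 0.139, high: 0.209, dist: beta}
  test_sensitivity:  {base: 0.991, low: 0.793, high: 1.000, dist: beta}
  test_specificity:  {base: 0.999, low: 0.799, high: 1.000, dist: beta}
  avoid_screening:   {base: 0.050, low: 0.040, high: 0.060, dist: beta}
  mri_uptake:        {base: 0.750, low: 0.600, high: 0.900, dist: beta}
  or_bc:
    ATM:   {base: 2.97, low: 1.67, high: 5.68,  dist: log_normal}
    CHEK2: {base: 2.19, low: 1.40, high: 3.56,  dist: log_normal}
    MSH6:  {base: 2.59, low: 1.35, high: 5.44,  dist: log_normal}
    PALB2: {base: 5.53, low: 2.24, high: 17.65, dist: log_normal}
  or_oc:
    ATM:    {base: 2.85,  low: 1.30,  high: 6.32,   dist: log_normal}
    MSH6:   {base: 4.16,  low: 1.95,  high: 9.47,   dist: log_normal}
    RAD51C: {base: 18.38, low: 14.70, high: 184.00, dist: log_normal}
    TP53:   {base: 18.50, low: 2.56,  high: 808.10, dist: log_normal}
  hr_bc_rrm:
    BRCA1:    {base: 0, low: 0, high: 0, dist: fixed}
    BRCA2:    {base: 0, low: 0, high: 0, dist: fixed}
    nonBRCA:  {base: 0, low: 0, high: 0, dist: fixed}
  hr_bc_rrso:
    BRCA1:    {base: 0.63, low: 0.41, high: 0.96, dist: log_normal}
    BRCA2:    {base: 0.36, low: 0.16, high: 0.82, dist: log_normal}
    nonBRCA:  {base: 0.36, low: 0.16, high: 0.82, dist: log_normal}
  hr_oc_rrso:
    BRCA1:    {base: 0.31, low: 0.12, high: 0.82, dist: log_normal}
    BRCA2:    {base: 0, low: 0, high: 0, dist: fixed}
    nonBRCA:  {base: 0, low: 0, high: 0, dist: fixed}
  early_stage_mortality_reduction: {base: 0.943, low: 0.900, high: 1.000, dist: log_normal}
  rel_mort_bc:
    lt45:   {base: 0.119, low: 0.095, high: 0.143, dist: log_normal}
    a45_54: {base: 0.094, low: 0.075, high: 0.113, dist: log_normal}
    a55_64: {base: 0.099, low: 0.079, high: 0.119, dist: log_normal}
    a65_74: {base: 0.086, low: 0.069, high: 0.103, dist: log_normal}
    ge75:   {base: 0.129, low: 0.103, high: 0.155, dist: log_normal}
  rel_mort_oc:
    lt45:   {base: 0.235, low: 0.188, high: 0.282, dist: log_normal}
    a45_54: {base: 0.409, low: 0.327, high: 0.491, dist: log_normal}
    a55_64: {base: 0.505, low: 0.404, high: 0.606, dist: log_normal}
    a65_74: {base: 0.613, low: 0.490, high: 0.736, dist: log_normal}
    ge75:   {base: 0.791, low: 0.633, high: 0.949, dist: log_normal}
  uptake_ratio_rrm:  {base: 0.500, low: 0.400, high: 0.600, dist: log_normal}
  uptake_ratio_rrso: {base: 0.500, low: 0.400, high: 0.600, dist: log_normal}
  util_bc:      {base: 0.663, low: 0.530, high: 0.796, dist: beta}
  util_oc:      {base: 0.628, low: 0.502, high: 0.754, dist: beta}
  util_post_bc: {base: 0.810, low: 0.648, high: 0.972, dist: beta}
  util_post_oc: {base: 0.720, low: 0.576, high: 0.864, dist: beta}
  disutil_mastectomy:   {base: 0.030, low: 0.024, high: 0.036, dist: beta}
  disutil_oophorectomy: {base: 0.030, low: 0.024, high: 0.036, dist: beta}
  disutil_knowledge:    {base: 0.050, low: 0.040, high: 0.060, dist: beta}
  disutil_noncarrier_harm: {base: 0.030, low: 0.029, high: 0.032, dist: beta}
  cost_mastectomy:   {base: 22110, low: 17688, high: 26532, dist: normal}
  cost_oophorectomy: {base: 8476,  low: 6781,  high: 10171, dist: normal}
  cost_mammography:  {base: 228,   low: 182,   high: 274,   dist: normal}
  cost_mri:          {base: 1403,  low: 1122,  high: 1683,  dist: normal}
  cost_assay:        {base: 200,   low: 160,   high: 240,   dist: normal}
  cost_confirmation: {base: 200,   low: 160,   high: 240,   dist: normal}
  cost_bc_initial_lt65:    {base: 83633,  low: 66906,  high: 100360, dist: normal}
  cost_bc_continuing_lt65: {base: 8048,   low: 6438,   high: 9658,   dist: normal}
  cost_bc_lastyear_lt65:   {base: 68022,  low: 54418,  high: 81626,  dist: normal}
  cost_oc_initial_lt65:    {base: 133121, low: 106497, high: 159745, dist: normal}
  cost_oc_continuing_lt65: {base: 14635,  low: 11708,  high: 17562,  dist: normal}
  cost_oc_lastyear_lt65:   {base: 93005,  low: 74404,  high: 111606, dist: normal}
  cost_bc_initial_ge65:    {base: 83633,  low: 66906,  high: 100360, dist: normal}
  cost_bc_continuing_ge65: {base: 8048,   low: 6438,   high: 9658,   dist: normal}
  cost_bc_lastyear_ge65:   {base: 68022,  low: 54418,  high: 81626,  dist: normal}
  cost_oc_initial_ge65:    {base: 133121, low: 106497, high: 159745, dist: normal}
  cost_oc_continuing_ge65: {base: 14635,  low: 11708,  high: 17562,  dist: normal}
  cost_oc_lastyear_ge65:   {base: 93005,  low: 74404,  high: 111606, dist: normal}
  cascade_inform: {base: 0.70, low: 0.56, high: 0.84, dist: beta}
  cascade_test:   {base: 0.20, low: 0.16, high: 0.24, dist: beta}
  discount_rate: {base: 0.03, low: 0.03, high: 0.03, dist: fixed}
  harm_affected_fraction: {base: 0.05, low: 0.05, high: 0.05, dist: fixed}
# Structural settings: never sampled in probabilistic sensitivity analysis.
settings:
  # Probability an incident breast cancer is detected at early stage, by
  # surveillance modality. These are modelling assumptions, not published
  # inputs; calibrate against registry stage distributions where available.
  stage_early_mammo_mri: 0.8
  stage_early_mammo: 0.5
  stage_early_undetected: 0.5
  # Ovarian cancer has no effective presymptomatic surveillance in the model:
  # a single early-stage detection probability applies in all states.
  stage_early_oc: 0.5
  # Cancer-specific excess mortality persists beyond 5 years post-diagnosis
  # (applies while in any cancer or post-cancer state) when TRUE.
  excess_mortality_persists: true
  # Reading of the early-stage breast cancer mortality parameter:
  # "reduction": early-stage excess mortality = (1 - value) * age-band excess
  # "multiplier": early-stage excess mortality = value * age-band excess
  early_stage_reading: reduction
  # One-time vs lifetime-annual reading of the noncarrier harm disutility.
  harm_one_time: true
  dirichlet_concentration: 100
  cascade_assumptions:
    n_sisters: 1
    n_daughters: 1
    maternal_gap: 27
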