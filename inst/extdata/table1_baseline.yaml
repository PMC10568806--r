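# Baseline model parameters, deterministic sensitivity ranges and
# probabilistic-sampling distributions for the first-line immunotherapy vs
# chemotherapy cost-effectiveness model.  Costs in 2022 USD; utilities on the
# 0-1 EQ-5D scale; drug prices in USD per mg.  Beta rows carry explicit
# (alpha, beta) plus the (mean, se) pair they were derived from; gamma rows
# carry (shape, scale) plus (mean, se).  dist: fixed means the value is not
# sampled in the probabilistic analysis (it may still have a deterministic
# range).
model:
  cycle_days: 42
  discount_rate: {base: 0.05, min: 0.0, max: 0.08, dist: fixed}
  wtp: 38142.56
  horizon: {survival_threshold: 0.01, cap_years: 40}
  integration: trapezoid
patient:
  bsa: {base: 1.80, min: 1.50, max: 1.90, dist: fixed}
  weight: 65
utility:
  pfs: {base: 0.7825, min: 0.75, max: 0.84, dist: beta,
        alpha: 245.001, beta: 63.176, mean: 0.795, se: 0.023}
  pd: {base: 0.64, min: 0.576, max: 0.704, dist: beta,
       alpha: 137.658, beta: 77.432, mean: 0.640, se: 0.033}
ae:
  incidence:
    P:
      diarrhoea: {base: 0.060, min: 0.048, max: 0.072, dist: beta,
                  alpha: 90.218, beta: 1413.409, mean: 0.060, se: 0.006}
      anaemia: {base: 0.050, min: 0.040, max: 0.060, dist: beta,
                alpha: 91.188, beta: 1732.572, mean: 0.050, se: 0.005}
      hypokalaemia: {base: 0.010, min: 0.008, max: 0.012, dist: beta,
                     alpha: 95.070, beta: 9411.890, mean: 0.010, se: 0.001}
      neutropenia: {base: 0.0, min: 0.0, max: 0.0, dist: fixed}
    C:
      diarrhoea: {base: 0.110, min: 0.088, max: 0.132, dist: beta,
                  alpha: 85.366, beta: 690.685, mean: 0.110, se: 0.011}
      anaemia: {base: 0.100, min: 0.080, max: 0.120, dist: beta,
                alpha: 86.336, beta: 777.024, mean: 0.100, se: 0.010}
      hypokalaemia: {base: 0.060, min: 0.048, max: 0.072, dist: beta,
                     alpha: 90.218, beta: 1413.409, mean: 0.060, se: 0.006}
      # half the neutrophil-count-decrease incidence is folded in
      neutropenia: {base: 0.235, min: 0.188, max: 0.282, dist: beta,
                    alpha: 73.236, beta: 238.405, mean: 0.235, se: 0.024}
  cost:
    diarrhoea: {base: 392.44, min: 313.95, max: 470.93, dist: gamma,
                shape: 16.000, scale: 24.527, mean: 392.439, se: 98.110}
    anaemia: {base: 724.64, min: 579.71, max: 869.57, dist: gamma,
              shape: 16.000, scale: 45.290, mean: 724.638, se: 181.160}
    hypokalaemia: {base: 157.28, min: 125.82, max: 188.73, dist: gamma,
                   shape: 16.000, scale: 9.830, mean: 157.275, se: 39.319}
    neutropenia: {base: 628.96, min: 503.17, max: 754.76, dist: gamma,
                  shape: 16.000, scale: 39.310, mean: 628.965, se: 157.241}
  disutility:  # one-off decrements for grade 3-4 events; sampled as
               # magnitudes and negated
    diarrhoea: {base: -0.090, min: -0.072, max: -0.108, dist: beta,
                alpha: 14.470, beta: 146.308, mean: -0.090, se: 0.023}
    anaemia: {base: -0.085, min: -0.068, max: -0.102, dist: beta,
              alpha: 14.555, beta: 156.680, mean: -0.085, se: 0.021}
    hypokalaemia: {base: -0.080, min: -0.064, max: -0.096, dist: beta,
                   alpha: 14.640, beta: 168.360, mean: -0.080, se: 0.020}
    neutropenia: {base: -0.0607, min: -0.049, max: -0.073, dist: beta,
                  alpha: 14.968, beta: 231.623, mean: -0.061, se: 0.015}
prices:  # USD per mg
  pembrolizumab: {base: 179.18, dist: fixed}
  oxaliplatin: {base: 3.4, min: 2.72, max: 4.08, dist: gamma,
                shape: 16.000, scale: 0.213, mean: 3.400, se: 0.850}
  leucovorin: {base: 0.25, min: 0.2, max: 0.3, dist: gamma,
               shape: 16.000, scale: 0.016, mean: 0.250, se: 0.063}
  fluorouracil: {base: 0.29, min: 0.232, max: 0.348, dist: gamma,
                 shape: 16.000, scale: 0.018, mean: 0.290, se: 0.073}
  bevacizumab: {base: 15.0, min: 11.88, max: 15.0, dist: gamma,
                shape: 16.000, scale: 0.840, mean: 13.440, se: 3.360}
  cetuximab: {base: 12.04, dist: fixed}
  irinotecan: {base: 17.73, min: 14.05, max: 24.9, dist: gamma,
               shape: 16.000, scale: 1.217, mean: 19.475, se: 4.869}
  nivolumab: {base: 96.2, dist: fixed}
  capecitabine: {base: 0.04, min: 0.01, max: 0.04, dist: gamma,
                 shape: 16.000, scale: 0.002, mean: 0.025, se: 0.006}
costs:
  administration: {base: 310.16, min: 248.13, max: 372.19, dist: gamma,
                   shape: 16.000, scale: 19.385, mean: 310.160, se: 77.540}
  followup: {base: 31.33, min: 25.06, max: 37.60, dist: gamma,
             shape: 16.000, scale: 1.958, mean: 31.330, se: 7.833}
  bsc: {base: 0.0, dist: fixed}  # best supportive care assumed free
mixes:
  # observed first-line regimen shares in the chemotherapy arm
  firstline_C:
    mfolfox: 0.0769
    mfolfox_bev: 0.4476
    mfolfox_cet: 0.0350
    folfiri: 0.1119
    folfiri_bev: 0.2517
    folfiri_cet: 0.0769
  # class shares of treatment after progression, per arm
  subsequent:
    P:
      pembrolizumab: {base: 0.100, min: 0.080, max: 0.120, dist: beta,
                      alpha: 86.336, beta: 777.024, mean: 0.100, se: 0.010}
      other_ici: {base: 0.075, min: 0.060, max: 0.090, dist: beta,
                  alpha: 88.762, beta: 1094.731, mean: 0.075, se: 0.008}
      chemotherapy: {base: 0.438, min: 0.350, max: 0.525, dist: beta,
                     alpha: 53.585, beta: 68.895, mean: 0.438, se: 0.045}
      vegf_inhibitor: {base: 0.275, min: 0.220, max: 0.330, dist: beta,
                       alpha: 69.354, beta: 182.842, mean: 0.275, se: 0.028}
      egfr_inhibitor: {base: 0.113, min: 0.090, max: 0.135, dist: beta,
                       alpha: 85.123, beta: 671.526, mean: 0.113, se: 0.011}
    C:
      pembrolizumab: {base: 0.427, min: 0.342, max: 0.513, dist: beta,
                      alpha: 54.557, beta: 73.068, mean: 0.427, se: 0.044}
      other_ici: {base: 0.282, min: 0.226, max: 0.339, dist: beta,
                  alpha: 68.632, beta: 174.362, mean: 0.282, se: 0.029}
      chemotherapy: {base: 0.153, min: 0.122, max: 0.183, dist: beta,
                     alpha: 81.225, beta: 450.797, mean: 0.153, se: 0.016}
      vegf_inhibitor: {base: 0.099, min: 0.079, max: 0.119, dist: beta,
                       alpha: 86.410, beta: 784.338, mean: 0.099, se: 0.010}
      egfr_inhibitor: {base: 0.038, min: 0.031, max: 0.046, dist: beta,
                      alpha: 92.336, beta: 2326.872, mean: 0.038, se: 0.004}
subsequent_ici_cap_cycles: 17.4  # two years of 42-day cycles
pap:
  enabled: false
  annual_cost: 11200
  cap_total: 22400
dosing:
  pembrolizumab: {dose_mg: 200, admin_per_cycle: 2, max_administrations: 35,
                  attendances_per_cycle: 2}
  chemo_admin_per_cycle: 3          # q2w backbones in a 42-day cycle
  chemo_attendances_per_cycle: 3
  cetuximab_extra_attendances: 6    # weekly infusion visits
  folfox: {oxaliplatin_mg_m2: 85, leucovorin_mg_m2: 400,
           fluorouracil_mg_m2: 2800}
  folfiri: {irinotecan_mg_m2: 180, leucovorin_mg_m2: 400,
            fluorouracil_mg_m2: 2800}
  bevacizumab_mg_kg: 5
  cetuximab: {weekly_mg_m2: 250, loading_mg_m2: 400, weekly_per_cycle: 6}
  # second-line regimens (standard q3w schedules, two courses per cycle)
  capecitabine_mg_m2_course: 28000  # 1000 mg/m2 twice daily, days 1-14
  capox_oxaliplatin_mg_m2: 130
  capiri_irinotecan_mg_m2: 200
  subsequent_admin_per_cycle: 2
  nivolumab: {dose_mg: 240, admin_per_cycle: 3}
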