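# Default aggregated PEW scoring table: seven parameters, subscore maxima
# summing to 26, alert at a total of 9 or more. Band cut-offs are a
# structurally valid default for simulation and testing; edit to match a
# local early-warning chart before any clinical use.
alert_threshold: 9
max_total: 26
age_bands:
- max_age_months: 12
  parameters:
    respiratory_rate:
    - [-.inf, 10, 4]
    - [10, 15, 3]
    - [15, 25, 1]
    - [25, 50, 0]
    - [50, 60, 1]
    - [60, 70, 2]
    - [70, 80, 3]
    - [80, .inf, 4]
    respiratory_distress:
    - [-.inf, 1, 0]
    - [1, 2, 1]
    - [2, 3, 2]
    - [3, .inf, 3]
    spo2:
    - [-.inf, 80, 4]
    - [80, 85, 3]
    - [85, 90, 2]
    - [90, 94, 1]
    - [94, .inf, 0]
    inspired_oxygen:
    - [-.inf, 0.22, 0]
    - [0.22, 0.3, 1]
    - [0.3, 0.4, 2]
    - [0.4, 0.6, 3]
    - [0.6, .inf, 4]
    heart_rate:
    - [-.inf, 60, 4]
    - [60, 80, 3]
    - [80, 100, 1]
    - [100, 160, 0]
    - [160, 180, 1]
    - [180, 200, 2]
    - [200, 220, 3]
    - [220, .inf, 4]
    systolic_bp:
    - [-.inf, 45, 4]
    - [45, 55, 3]
    - [55, 65, 2]
    - [65, 70, 1]
    - [70, 100, 0]
    - [100, 110, 1]
    - [110, 125, 2]
    - [125, .inf, 3]
    capillary_refill_seconds:
    - [-.inf, 2, 0]
    - [2, 3, 1]
    - [3, 5, 2]
    - [5, .inf, 3]
- max_age_months: 60
  parameters:
    respiratory_rate:
    - [-.inf, 8, 4]
    - [8, 12, 3]
    - [12, 20, 1]
    - [20, 40, 0]
    - [40, 50, 1]
    - [50, 60, 2]
    - [60, 70, 3]
    - [70, .inf, 4]
    respiratory_distress:
    - [-.inf, 1, 0]
    - [1, 2, 1]
    - [2, 3, 2]
    - [3, .inf, 3]
    spo2:
    - [-.inf, 80, 4]
    - [80, 85, 3]
    - [85, 90, 2]
    - [90, 94, 1]
    - [94, .inf, 0]
    inspired_oxygen:
    - [-.inf, 0.22, 0]
    - [0.22, 0.3, 1]
    - [0.3, 0.4, 2]
    - [0.4, 0.6, 3]
    - [0.6, .inf, 4]
    heart_rate:
    - [-.inf, 50, 4]
    - [50, 65, 3]
    - [65, 80, 1]
    - [80, 140, 0]
    - [140, 160, 1]
    - [160, 180, 2]
    - [180, 200, 3]
    - [200, .inf, 4]
    systolic_bp:
    - [-.inf, 50, 4]
    - [50, 60, 3]
    - [60, 70, 2]
    - [70, 80, 1]
    - [80, 110, 0]
    - [110, 120, 1]
    - [120, 135, 2]
    - [135, .inf, 3]
    capillary_refill_seconds:
    - [-.inf, 2, 0]
    - [2, 3, 1]
    - [3, 5, 2]
    - [5, .inf, 3]
- max_age_months: .inf
  parameters:
    respiratory_rate:
    - [-.inf, 6, 4]
    - [6, 10, 3]
    - [10, 12, 1]
    - [12, 25, 0]
    - [25, 35, 1]
    - [35, 45, 2]
    - [45, 55, 3]
    - [55, .inf, 4]
    respiratory_distress:
    - [-.inf, 1, 0]
    - [1, 2, 1]
    - [2, 3, 2]
    - [3, .inf, 3]
    spo2:
    - [-.inf, 80, 4]
    - [80, 85, 3]
    - [85, 90, 2]
    - [90, 94, 1]
    - [94, .inf, 0]
    inspired_oxygen:
    - [-.inf, 0.22, 0]
    - [0.22, 0.3, 1]
    - [0.3, 0.4, 2]
    - [0.4, 0.6, 3]
    - [0.6, .inf, 4]
    heart_rate:
    - [-.inf, 40, 4]
    - [40, 50, 3]
    - [50, 60, 1]
    - [60, 120, 0]
    - [120, 140, 1]
    - [140, 160, 2]
    - [160, 180, 3]
    - [180, .inf, 4]
    systolic_bp:
    - [-.inf, 60, 4]
    - [60, 70, 3]
    - [70, 80, 2]
    - [80, 90, 1]
    - [90, 120, 0]
    - [120, 135, 1]
    - [135, 150, 2]
    - [150, .inf, 3]
    capillary_refill_seconds:
    - [-.inf, 2, 0]
    - [2, 3, 1]
    - [3, 5, 2]
    - [5, .inf, 3]
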