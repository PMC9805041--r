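# Simulation scenario grid: 33 fully-connected network configurations.
# n_treat: treatments in the network; n_min/n_max: participants per arm
# (uniform, shared across arms of a study); studies_per_comparison: studies
# generated per pairwise comparison (two_arm_complete) or total all-arm
# studies (all_arm_multi); tau: between-study SD of the log odds ratios;
# risk_min/risk_max: uniform range of the control-group risk.
- {id: 1,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 2, design: two_arm_complete, tau: 0.0, risk_min: 0.030, risk_max: 0.050}
- {id: 2,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 2, design: two_arm_complete, tau: 0.1, risk_min: 0.030, risk_max: 0.050}
- {id: 3,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 2, design: two_arm_complete, tau: 0.0, risk_min: 0.050, risk_max: 0.100}
- {id: 4,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 2, design: two_arm_complete, tau: 0.1, risk_min: 0.050, risk_max: 0.100}
- {id: 5,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 4, design: two_arm_complete, tau: 0.0, risk_min: 0.030, risk_max: 0.050}
- {id: 6,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 4, design: two_arm_complete, tau: 0.1, risk_min: 0.030, risk_max: 0.050}
- {id: 7,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 4, design: two_arm_complete, tau: 0.0, risk_min: 0.050, risk_max: 0.100}
- {id: 8,  n_treat: 5, n_min: 30,  n_max: 60,  studies_per_comparison: 4, design: two_arm_complete, tau: 0.1, risk_min: 0.050, risk_max: 0.100}
- {id: 9,  n_treat: 8, n_min: 30,  n_max: 60,  studies_per_comparison: 2, design: two_arm_complete, tau: 0.0, risk_min: 0.030, risk_max: 0.050}
- {id: 10, n_treat: 8, n_min: 30,  n_max: 60,  studies_per_comparison: 2, design: two_arm_complete, tau: 0.1, risk_min: 0.030, risk_max: 0.050}
- {id: 11, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 2, design: two_arm_complete, tau: 0.0, risk_min: 0.010, risk_max: 0.020}
- {id: 12, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 2, design: two_arm_complete, tau: 0.1, risk_min: 0.010, risk_max: 0.020}
- {id: 13, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 2, design: two_arm_complete, tau: 0.0, risk_min: 0.005, risk_max: 0.010}
- {id: 14, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 2, design: two_arm_complete, tau: 0.1, risk_min: 0.005, risk_max: 0.010}
- {id: 15, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 4, design: two_arm_complete, tau: 0.0, risk_min: 0.005, risk_max: 0.010}
- {id: 16, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 4, design: two_arm_complete, tau: 0.1, risk_min: 0.005, risk_max: 0.010}
- {id: 17, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.010, risk_max: 0.020}
- {id: 18, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.010, risk_max: 0.020}
- {id: 19, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.005, risk_max: 0.010}
- {id: 20, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.005, risk_max: 0.010}
- {id: 21, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.005, risk_max: 0.050}
- {id: 22, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.005, risk_max: 0.050}
- {id: 23, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.005, risk_max: 0.100}
- {id: 24, n_treat: 3, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.005, risk_max: 0.100}
- {id: 25, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.010, risk_max: 0.020}
- {id: 26, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.010, risk_max: 0.020}
- {id: 27, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.005, risk_max: 0.010}
- {id: 28, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.005, risk_max: 0.010}
- {id: 29, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.005, risk_max: 0.050}
- {id: 30, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.005, risk_max: 0.050}
- {id: 31, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.0, risk_min: 0.005, risk_max: 0.100}
- {id: 32, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 8, design: all_arm_multi,    tau: 0.1, risk_min: 0.005, risk_max: 0.100}
- {id: 33, n_treat: 5, n_min: 100, n_max: 200, studies_per_comparison: 4, design: two_arm_complete, tau: 0.0, risk_min: 0.001, risk_max: 0.003}
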