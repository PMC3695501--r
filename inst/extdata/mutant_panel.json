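[
  {"label": "wt",    "k_bind": 3528, "k_dim": 717, "k_hyd": 201,   "k_diss": 12.4, "k_pi_rel": 9.6,  "modification_activity": 100, "hydrolase_class": "fast"},
  {"label": "T250S", "k_bind": 3452, "k_dim": 356, "k_hyd": 163,   "k_diss": 2.6,  "k_pi_rel": 2.7,  "modification_activity": 19,  "hydrolase_class": "fast"},
  {"label": "R256A", "k_bind": 2633, "k_dim": 207, "k_hyd": 44,    "k_diss": 5.1,  "k_pi_rel": 5.5,  "modification_activity": 97,  "hydrolase_class": "fast"},
  {"label": "L274G", "k_bind": 2761, "k_dim": 418, "k_hyd": 30,    "k_diss": 11.1, "k_pi_rel": 1.6,  "modification_activity": 0,   "hydrolase_class": "fast"},
  {"label": "L274A", "k_bind": 3222, "k_dim": 378, "k_hyd": 56,    "k_diss": 12.0, "k_pi_rel": 1.5,  "modification_activity": 0,   "hydrolase_class": "fast"},
  {"label": "G285A", "k_bind": 3196, "k_dim": 280, "k_hyd": 42,    "k_diss": 10.3, "k_pi_rel": 0.8,  "modification_activity": 0,   "hydrolase_class": "fast"},
  {"label": "T251A", "k_bind": 2743, "k_dim": 236, "k_hyd": 0.01,  "k_diss": null, "k_pi_rel": null, "modification_activity": 0,   "hydrolase_class": "slow"},
  {"label": "R252A", "k_bind": 3935, "k_dim": 755, "k_hyd": 6.74,  "k_diss": 1.3,  "k_pi_rel": 0.8,  "modification_activity": 5,   "hydrolase_class": "slow"},
  {"label": "D253A", "k_bind": 3389, "k_dim": 266, "k_hyd": 5.71,  "k_diss": 1.7,  "k_pi_rel": 0.3,  "modification_activity": 0,   "hydrolase_class": "slow"},
  {"label": "L274Q", "k_bind": 3254, "k_dim": 222, "k_hyd": 2.13,  "k_diss": 1.9,  "k_pi_rel": 2.4,  "modification_activity": 19,  "hydrolase_class": "slow"},
  {"label": "R275A", "k_bind": 3216, "k_dim": 218, "k_hyd": 12.43, "k_diss": 1.9,  "k_pi_rel": 2.0,  "modification_activity": 51,  "hydrolase_class": "slow"},
  {"label": "E282A", "k_bind": 2241, "k_dim": 104, "k_hyd": 0.02,  "k_diss": null, "k_pi_rel": null, "modification_activity": 0,   "hydrolase_class": "slow"},
  {"label": "G285I", "k_bind": 2323, "k_dim": 151, "k_hyd": 0.33,  "k_diss": null, "k_pi_rel": null, "modification_activity": 0,   "hydrolase_class": "slow"},
  {"label": "R288A", "k_bind": 3314, "k_dim": 341, "k_hyd": 8.22,  "k_diss": 2.3,  "k_pi_rel": 0.9,  "modification_activity": 11,  "hydrolase_class": "slow"}
]
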