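{
  "comment": "Published stepwise-regression equations linking the 10 main ecological factors (X1..X10, see main_factors.csv for the layer mapping) to the 22 functional factors.",
  "covariates": ["X1", "X2", "X3", "X4", "X5", "X6", "X7", "X8", "X9", "X10"],
  "categories": {
    "lobetyolin": "index",
    "atractylenolide_III": "index",
    "syringin": "index",
    "polysaccharides": "effective",
    "oligosaccharides": "effective",
    "alcohol_extract": "effective",
    "amino_acid": "nutritional",
    "protein": "nutritional",
    "fat": "nutritional",
    "dietary_fiber": "nutritional",
    "total_nutrient_elements": "nutritional",
    "peak_1": "peak",
    "peak_4": "peak",
    "peak_5": "peak",
    "peak_6": "peak",
    "peak_9": "peak",
    "peak_10": "peak",
    "peak_11": "peak",
    "peak_12": "peak",
    "peak_14": "peak",
    "peak_15": "peak",
    "peak_19": "peak"
  },
  "models": [
    {"response": "lobetyolin", "intercept": 16.969,
     "coefficients": [-0.040, -0.001, -0.004, 0.022, 0.052, -0.122, 0.001, 0.001, -0.037, 0.079]},
    {"response": "atractylenolide_III", "intercept": 52.840,
     "coefficients": [1.287, -0.007, 2.748, 1.785, -0.460, -1.695, 0.143, 0.013, -2.351, 0.269]},
    {"response": "syringin", "intercept": 264.857,
     "coefficients": [-4.237, -0.026, 0.424, 1.910, 2.372, -0.712, 0.161, 0.019, -1.113, -0.547]},
    {"response": "polysaccharides", "intercept": 172.485,
     "coefficients": [0.169, -0.009, -1.378, -1.281, -0.136, -0.273, 0.030, -0.006, -0.887, 0.444]},
    {"response": "oligosaccharides", "intercept": 25.193,
     "coefficients": [0.148, 0.001, 0.684, -0.648, 0.436, -1.116, -0.033, -0.001, 0.045, -0.297]},
    {"response": "alcohol_extract", "intercept": -89.105,
     "coefficients": [0.459, 0.013, 0.579, 0.489, 0.417, -1.017, -0.015, -0.003, 0.507, 1.623]},
    {"response": "amino_acid", "intercept": -157.827,
     "coefficients": [-1.546, 0.006, -0.239, 3.612, -2.817, 6.634, 0.121, 0.029, 2.206, -3.624]},
    {"response": "protein", "intercept": -53.384,
     "coefficients": [-0.065, 0.003, -0.130, 0.633, -0.373, 0.984, -0.030, 0.003, 0.532, -0.348]},
    {"response": "fat", "intercept": -2.803,
     "coefficients": [-0.013, -0.012, 0.064, 0.085, 0.015, -0.024, 0.001, 0.001, -0.001, 0.002]},
    {"response": "dietary_fiber", "intercept": 61.543,
     "coefficients": [-0.145, -0.007, 0.495, 1.445, -1.141, 1.778, -0.013, 0.010, 0.724, -0.259]},
    {"response": "total_nutrient_elements", "intercept": 71.313,
     "coefficients": [0.045, -0.007, -0.528, 0.689, 0.052, -0.286, 0.004, 0.005, -0.730, 0.173]},
    {"response": "peak_1", "intercept": -136.384,
     "coefficients": [2.682, 0.032, -0.351, -7.131, -1.305, 2.033, -0.162, -0.062, 4.247, -0.098]},
    {"response": "peak_4", "intercept": -21.402,
     "coefficients": [0.050, 0.003, 0.684, -0.432, 0.413, -0.586, -0.009, -0.003, -0.626, -0.589]},
    {"response": "peak_5", "intercept": 103.915,
     "coefficients": [0.936, 0.006, 0.493, -4.608, -0.667, -0.099, 0.027, -0.021, 0.351, -0.498]},
    {"response": "peak_6", "intercept": 93.376,
     "coefficients": [-0.279, -0.015, -1.142, 2.395, -0.215, 0.320, -0.043, 0.021, 1.110, -0.378]},
    {"response": "peak_9", "intercept": 84.261,
     "coefficients": [1.283, 0.001, -1.098, -1.959, -2.461, 2.903, 0.060, -0.005, 3.601, -1.513]},
    {"response": "peak_10", "intercept": 493.755,
     "coefficients": [-0.739, -0.007, -4.109, -10.749, -2.510, 4.080, 0.401, -0.030, 2.683, 0.788]},
    {"response": "peak_11", "intercept": 49.649,
     "coefficients": [-0.633, 0.002, 0.847, -2.428, 0.053, 0.480, 0.027, -0.008, 2.062, -0.108]},
    {"response": "peak_12", "intercept": 17.325,
     "coefficients": [-0.848, 0.008, 1.135, -3.020, -0.031, 0.937, -0.045, -0.014, 1.016, 0.292]},
    {"response": "peak_14", "intercept": 337.317,
     "coefficients": [-2.314, 0.015, 2.725, -17.072, 6.403, -6.896, 0.036, -0.076, -2.496, 3.776]},
    {"response": "peak_15", "intercept": 111.734,
     "coefficients": [-0.599, -0.005, -1.096, -1.376, 0.266, 0.175, 0.051, -0.003, 0.208, 0.965]},
    {"response": "peak_19", "intercept": 51.287,
     "coefficients": [-0.246, -0.002, -0.276, -0.534, -0.050, 0.158, 0.009, -0.001, 0.103, 0.293]}
  ]
}
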