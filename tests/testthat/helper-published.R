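# Published reference values used as frozen expectations in the tests.
# Columns of the asymptotic grids: theta, then upper-tail points at
# alpha = 0.50, 0.25, 0.15, 0.10, 0.05, 0.025, 0.01.
published_alpha_levels <- c(0.50, 0.25, 0.15, 0.10, 0.05, 0.025, 0.01)

published_w2_points <- rbind(
  c(0.05, 0.075, 0.119, 0.152, 0.179, 0.228, 0.278, 0.346),
  c(0.1, 0.077, 0.122, 0.156, 0.184, 0.234, 0.286, 0.357),
  c(0.15, 0.077, 0.125, 0.16, 0.189, 0.242, 0.296, 0.37),
  c(0.2, 0.077, 0.127, 0.164, 0.195, 0.25, 0.307, 0.385),
  c(0.25, 0.076, 0.128, 0.168, 0.201, 0.259, 0.319, 0.401),
  c(0.3, 0.073, 0.128, 0.17, 0.205, 0.267, 0.331, 0.418),
  c(0.4, 0.065, 0.124, 0.17, 0.208, 0.277, 0.349, 0.447),
  c(0.45, 0.06, 0.119, 0.166, 0.205, 0.277, 0.351, 0.453),
  c(0.48, 0.057, 0.114, 0.162, 0.202, 0.274, 0.35, 0.453),
  c(0.49, 0.055, 0.113, 0.161, 0.201, 0.273, 0.348, 0.452),
  c(0.5, 0.054, 0.112, 0.159, 0.199, 0.272, 0.347, 0.45),
  c(0.51, 0.053, 0.11, 0.158, 0.198, 0.27, 0.345, 0.449),
  c(0.52, 0.052, 0.108, 0.156, 0.196, 0.268, 0.343, 0.446),
  c(0.55, 0.048, 0.103, 0.149, 0.189, 0.26, 0.335, 0.436),
  c(0.6, 0.041, 0.092, 0.137, 0.174, 0.242, 0.313, 0.409),
  c(0.65, 0.034, 0.08, 0.121, 0.155, 0.217, 0.281, 0.368),
  c(0.7, 0.026, 0.067, 0.102, 0.131, 0.185, 0.24, 0.315),
  c(0.75, 0.02, 0.052, 0.081, 0.104, 0.147, 0.192, 0.253),
  c(0.8, 0.014, 0.038, 0.058, 0.076, 0.107, 0.14, 0.184),
  c(0.85, 0.008, 0.024, 0.037, 0.048, 0.068, 0.088, 0.116),
  c(0.9, 0.004, 0.011, 0.018, 0.023, 0.033, 0.043, 0.057),
  c(0.95, 0.001, 0.003, 0.005, 0.006, 0.009, 0.012, 0.016)
)

published_a2_points <- rbind(
  c(0.05, 0.48, 0.727, 0.917, 1.067, 1.325, 1.597, 1.982),
  c(0.1, 0.466, 0.719, 0.912, 1.065, 1.331, 1.611, 2.004),
  c(0.15, 0.452, 0.709, 0.905, 1.062, 1.335, 1.622, 2.023),
  c(0.2, 0.436, 0.697, 0.897, 1.057, 1.337, 1.631, 2.04),
  c(0.25, 0.42, 0.683, 0.886, 1.05, 1.336, 1.637, 2.054),
  c(0.3, 0.402, 0.668, 0.874, 1.04, 1.333, 1.639, 2.064),
  c(0.35, 0.383, 0.651, 0.858, 1.027, 1.325, 1.638, 2.07),
  c(0.4, 0.364, 0.631, 0.84, 1.011, 1.314, 1.631, 2.069),
  c(0.45, 0.343, 0.609, 0.819, 0.991, 1.297, 1.618, 2.061),
  c(0.48, 0.33, 0.594, 0.804, 0.977, 1.285, 1.607, 2.052),
  c(0.49, 0.325, 0.589, 0.799, 0.972, 1.28, 1.603, 2.048),
  c(0.5, 0.321, 0.584, 0.794, 0.967, 1.275, 1.598, 2.044),
  c(0.51, 0.316, 0.579, 0.788, 0.961, 1.27, 1.593, 2.039),
  c(0.52, 0.311, 0.573, 0.783, 0.956, 1.264, 1.588, 2.033),
  c(0.55, 0.297, 0.556, 0.764, 0.937, 1.245, 1.569, 2.014),
  c(0.6, 0.272, 0.524, 0.729, 0.901, 1.207, 1.528, 1.97),
  c(0.65, 0.245, 0.488, 0.688, 0.856, 1.157, 1.473, 1.906),
  c(0.7, 0.217, 0.447, 0.64, 0.802, 1.093, 1.398, 1.816),
  c(0.75, 0.187, 0.4, 0.582, 0.735, 1.01, 1.299, 1.693),
  c(0.8, 0.154, 0.346, 0.512, 0.652, 0.903, 1.166, 1.525),
  c(0.85, 0.119, 0.283, 0.426, 0.547, 0.763, 0.989, 1.297),
  c(0.9, 0.082, 0.208, 0.319, 0.411, 0.578, 0.752, 0.989),
  c(0.95, 0.043, 0.117, 0.181, 0.235, 0.331, 0.432, 0.57)
)

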