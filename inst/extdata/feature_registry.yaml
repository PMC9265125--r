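# Canonical radiomic feature registry: the single source of truth for
# family membership, per-family feature order and counts. The extraction
# code refuses to run if the counts differ from 8/18/20/11/13/13/16/5.
version: "1.0"
families:
  MORPH:
    - volume
    - approx_volume
    - surface_area
    - surface_to_volume_ratio
    - sphericity
    - compactness_1
    - compactness_2
    - max_3d_diameter
  INT:
    - mean
    - median
    - minimum
    - maximum
    - range
    - variance
    - standard_deviation
    - skewness
    - kurtosis
    - energy
    - root_mean_square
    - mean_absolute_deviation
    - robust_mean_absolute_deviation
    - interquartile_range
    - percentile_10
    - percentile_90
    - coefficient_of_variation
    - quartile_coefficient_of_dispersion
  HIST:
    - mean
    - variance
    - skewness
    - kurtosis
    - median
    - minimum_level
    - maximum_level
    - mode
    - interquartile_range
    - range
    - percentile_10
    - percentile_90
    - mean_absolute_deviation
    - robust_mean_absolute_deviation
    - coefficient_of_variation
    - quartile_coefficient_of_dispersion
    - entropy
    - uniformity
    - max_histogram_gradient
    - max_histogram_gradient_level
  GLCM:
    - joint_energy
    - joint_entropy
    - contrast
    - dissimilarity
    - inverse_difference
    - inverse_difference_moment
    - correlation
    - joint_variance
    - sum_average
    - sum_entropy
    - difference_entropy
  GLRLM:
    - short_run_emphasis
    - long_run_emphasis
    - low_gray_level_run_emphasis
    - high_gray_level_run_emphasis
    - short_run_low_gray_level_emphasis
    - short_run_high_gray_level_emphasis
    - long_run_low_gray_level_emphasis
    - long_run_high_gray_level_emphasis
    - gray_level_non_uniformity
    - run_length_non_uniformity
    - run_percentage
    - gray_level_variance
    - run_length_variance
  GLSZM:
    - small_zone_emphasis
    - large_zone_emphasis
    - low_gray_level_zone_emphasis
    - high_gray_level_zone_emphasis
    - small_zone_low_gray_level_emphasis
    - small_zone_high_gray_level_emphasis
    - large_zone_low_gray_level_emphasis
    - large_zone_high_gray_level_emphasis
    - gray_level_non_uniformity
    - zone_size_non_uniformity
    - zone_percentage
    - gray_level_variance
    - zone_size_variance
  NGLDM:
    - low_dependence_emphasis
    - high_dependence_emphasis
    - low_gray_level_count_emphasis
    - high_gray_level_count_emphasis
    - low_dependence_low_gray_level_emphasis
    - low_dependence_high_gray_level_emphasis
    - high_dependence_low_gray_level_emphasis
    - high_dependence_high_gray_level_emphasis
    - gray_level_non_uniformity
    - gray_level_non_uniformity_normalised
    - dependence_count_non_uniformity
    - dependence_count_non_uniformity_normalised
    - gray_level_variance
    - dependence_count_variance
    - dependence_count_entropy
    - dependence_count_energy
  NGTDM:
    - coarseness
    - contrast
    - busyness
    - complexity
    - strength
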