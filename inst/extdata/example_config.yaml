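# Example run configuration for run_pipeline(); any key left out falls back
# to the documented default.
seed: 1
output_dir: null          # set a directory to write stage artifacts
simulate:
  n_barrels: 46
  n_classes: 5
  n_informative: 10
  fold_change: 4
  n_samples_per_class: 10
  n_technical_reps: 4
outliers:
  alpha: 0.05
  drop_threshold: 2
  grouping: class
cv:
  classifiers:
    - gaussian_naive_bayes
    - k_nearest_neighbours
    - linear_discriminant_analysis
    - adaboost
    - svc_linear
    - svc_rbf
    - dummy_uniform
    - dummy_stratified
  k_outer: 5
  k_inner: 3
selection:
  k_features: 5
  n_trees: 500
  n_permutations: 50
compare: true
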