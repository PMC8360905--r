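# shared fixtures and oracles, built in code

opt <- function(v, p) reward_option(v, p)

# a bare condition row usable by simulate_condition()
cond_pair <- function(va, pa, vb, pb, label = "test") {
  data.frame(label = label, volume_a = va, prob_a = pa,
             volume_b = vb, prob_b = pb, stringsAsFactors = FALSE)
}

# Monte-Carlo choice frequency of option A
choice_freq <- function(spec, a, b, n, seed = 1) {
  set.seed(seed)
  mean(choose_option(spec, a, b, n))
}

# binomial 3-SE tolerance around probability p at n draws (plus a grain for
# discreteness when p is at the boundary)
three_se <- function(p, n) 3 * sqrt(p * (1 - p) / n) + 2 / n

# observed per-condition mean performances generated by a model
observe_means <- function(spec, keys, n_mice, n_choices, seed) {
  perf <- vapply(seq_len(nrow(keys)), function(j) {
    cond <- condition_row(keys$experiment[j], keys$condition[j])
    mean(predict_performance(spec, cond, n_mice, n_choices,
                             seed = substream_seed(seed, j))$performances)
  }, numeric(1))
  data.frame(experiment = keys$experiment, condition = keys$condition,
             performance = perf, stringsAsFactors = FALSE)
}

# hand-built performance-table row
perf_row <- function(mouse, experiment, condition, performance,
                     n = 100, flagged = FALSE) {
  data.frame(mouse_id = mouse, experiment = experiment,
             condition = condition,
             n_high = round(performance * n), n_low = n - round(performance * n),
             performance = performance, flagged = flagged,
             stringsAsFactors = FALSE)
}
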