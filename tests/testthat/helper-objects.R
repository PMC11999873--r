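# small constructors used by pipeline tests

new_kappa_estimate_for_test <- function(kappa, stderr) {
    sleflow:::new_kappa_estimate(kappa, stderr, "left_passage",
                                 diagnostics = list())
}

trace_points_for_test <- function(trace) sleflow:::trace_points(trace)
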