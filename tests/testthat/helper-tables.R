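# shared fixtures built in code

# reference table used throughout: margins all 200, so S and E are
# independent in the full sample while the case distribution is not
ref_table <- function() {
  two_by_four_table(a = 10, B = 190, c = 20, D = 180,
                    e = 30, F = 170, g = 120, H = 80)
}

uniform_table <- function(k = 10) {
  two_by_four_table(k, k, k, k, k, k, k, k)
}

# random strictly positive table; counts 5..200 avoid zero-cell paths
random_table <- function() {
  x <- sample(5:200, 8, replace = TRUE)
  two_by_four_table(x[1], x[2], x[3], x[4], x[5], x[6], x[7], x[8])
}

cases_of <- function(t) case_only_counts(t$a, t$c, t$e, t$g)

# marginal (collapsed 2x2) disease odds ratio for a single factor,
# independent oracle for fit_single_effect
collapsed_or <- function(t, which = c("S", "E")) {
  which <- match.arg(which)
  if (which == "S") {
    (t$c + t$g) * (t$B + t$F) / ((t$a + t$e) * (t$D + t$H))
  } else {
    (t$e + t$g) * (t$B + t$D) / ((t$a + t$c) * (t$F + t$H))
  }
}

case_subset <- function(d) {
  out <- d[d$D == 1, , drop = FALSE]
  attr(out, "covariates") <- attr(d, "covariates")
  out
}
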