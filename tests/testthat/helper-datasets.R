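# Builders for small in-memory datasets used across the suite.

# untruncated dataset: every attainment falls inside an unbounded window that
# opened long before, so the likelihood reduces to plain exponential
make_untruncated <- function(x, country = "US", sex = NULL) {
  n <- length(x)
  mrad_data(
    data.frame(id = as.character(seq_len(n)), country = country,
               sex = if (is.null(sex)) "unknown" else sex,
               t = seq(1950, 1960, length.out = max(n, 2))[seq_len(n)], x = x),
    data.frame(country = unique(country), b = 1900, e = Inf))
}

# one-country dataset with explicit t/x and a bounded window
make_windowed <- function(t, x, b, e, country = "US") {
  n <- length(x)
  mrad_data(
    data.frame(id = as.character(seq_len(n)), country = country, t = t, x = x),
    data.frame(country = country, b = b, e = e))
}
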