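# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# 61-measurement single-diffusion-time protocol (10 dirs x 6 b + 1 b0).
scheme_1delta <- function() {
  if (is.null(.fixture_env$s1))
    .fixture_env$s1 <- build_protocol_scheme(Deltas = 10)
  .fixture_env$s1
}

# Full 305-measurement protocol over 5 diffusion times.
scheme_full <- function() {
  if (is.null(.fixture_env$s5))
    .fixture_env$s5 <- build_protocol_scheme()
  .fixture_env$s5
}
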