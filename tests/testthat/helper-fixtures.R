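# Shared in-code fixtures (no files on disk; everything is generated).

make_paired_tables <- function(n = 40, seed = 80) {
  set.seed(seed)
  ids <- sprintf("L%03d", seq_len(n))
  x <- stats::rnorm(n)
  static <- tibble::tibble(lesion_id = ids, patient_id = ids,
                           center_id = "c1",
                           outcome = sample(c("responding", "non-responding"),
                                            n, replace = TRUE),
                           fa = x, fb = stats::rnorm(n), fc = stats::rnorm(n))
  dtp <- static
  dtp$fa <- exp(x) # monotone transform
  dtp$fb <- -static$fb # sign flip
  dtp$fc <- stats::rnorm(n)
  list(static = static, dtp = dtp)
}
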