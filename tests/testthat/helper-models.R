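# shared model fixtures: the two plasmids used throughout, built in code

pbr322 <- plasmid_spec("pBR322", 4300)
ycp50 <- plasmid_spec("YCp50", 7900)
en43 <- energetics_model(pbr322) # sigma2 = 4300/2200
en79 <- energetics_model(ycp50)  # sigma2 = 7900/2200

# gate with the package calibration (p0 from the 0.50 one-step conversion,
# 1 + alpha from the 0.17/0.35 ratio pair)
gate_cal <- gate_model()

# gate small enough that neither capture nor release ever clips over a
# +/-15-state support of the 4.3-kb model (for exact oracle comparisons)
gate_tiny <- gate_model(p0 = 5e-4, pi0 = 0.01)

expect_distribution_ok <- function(d) {
  expect_s3_class(d, "lk_distribution")
  expect_equal(sum(d$fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(d$support) == 1L))
  expect_true(all(d$fractions >= 0))
}
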