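# Shared fixtures, built in code at test time.

write_temp_samples <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  samples <- file.path(dir, "samples.csv")
  aa <- file.path(dir, "aa.csv")
  writeLines(c(
    "sample_id,category,origin,bulk_d13c,bulk_d15n,cn_molar",
    "H1,human,archaeological,-18.4,14.5,3.2",
    "H2,human,archaeological,-19.7,12.4,3.6",
    "R1,rat,archaeological,,13.0,4.1"
  ), samples)
  writeLines(c(
    "sample_id,element,aa,mean,sd,n",
    "H1,N,Glx,18.1,0.4,6",
    "H1,N,Phe,11.5,0.4,6",
    "H1,C,Phe,-20.0,0.38,6",
    "H2,N,Glx,17.0,0.5,6",
    "H2,N,Phe,10.9,0.3,6"
  ), aa)
  list(samples = samples, aa = aa)
}

# two well-separated synthetic sources on the centered Leu/Phe/Val scale
two_distant_sources <- function(sd = 0.1) {
  training <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:8),
    Leu = c(rep(-2, 4), rep(2, 4)) + c(-.1, .1, -.05, .05, -.1, .1, -.05, .05) * sd * 10,
    Phe = c(rep(3, 4), rep(-3, 4)),
    Val = c(rep(-1, 4), rep(1, 4))
  )
  training <- center_patterns(training, c("Leu", "Phe", "Val"))
  assignment <- stats::setNames(rep(c("A", "B"), each = 4), training$sample_id)
  build_source_groups(training, assignment, c("Leu", "Phe", "Val"))
}
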