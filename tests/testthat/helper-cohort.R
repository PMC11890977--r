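# Small cohort fixtures built in code.

tiny_params <- function(...) {
  defaults <- list(n_nodes = 30, n_hc = 4, n_vci = 4, n_timepoints = 60,
                   backbone_k = 6, boost_nodes = c(3, 7, 11),
                   deficit_nodes = c(15, 20))
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

tiny_manifest <- function(n = 6) {
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("HC", "VCI"), length.out = n),
    age = seq(55, 74, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    education = rep(c(9, 12, 16), length.out = n),
    MMSE = 27, AVLT = 25, AVLT_N5 = 5, SDMT = 30, STT_B = 140, BNT = 23,
    sc_source = sprintf("S%02d_sc.txt", seq_len(n)),
    bold_source = sprintf("S%02d_bold.txt", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

write_tiny_manifest <- function(path, df = tiny_manifest()) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
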