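# Hand-built 6-feature QC fixture: exactly one violation of each filter
# rule (RSD, QC intensity, study missingness) plus three clean features.
make_filter_fixture <- function() {
  n_study <- 10; n_qc <- 10
  qc_vals <- list(
    f_rsd_bad  = c(2000, 9000, 25000, 4000, 30000, 12000, 21000, 7000,
                   26000, 15000),               # RSD ~ 66%
    f_int_bad  = rep(c(4000, 6000), c(6, 4)),   # < 5000 in 6/10 QCs
    f_miss_bad = rep(10000, n_qc),
    f_ok1      = rep(10000, n_qc),
    f_ok2      = seq(9000, 11000, length.out = n_qc),  # RSD ~ 6%
    f_ok3      = rep(20000, n_qc))
  study <- matrix(10000, n_study, 6,
                  dimnames = list(NULL, names(qc_vals)))
  study[1:8, "f_miss_bad"] <- NA  # 80% missing > 70%
  m <- rbind(study, do.call(cbind, qc_vals))
  sm <- data.frame(
    sample_id = c(sprintf("S%02d", 1:n_study), sprintf("Q%02d", 1:n_qc)),
    participant_id = c(rep(sprintf("P%02d", 1:5), each = 2), rep(NA, n_qc)),
    sex = c(rep("female", n_study), rep(NA, n_qc)),
    trial = c(rep("moderate", n_study), rep(NA, n_qc)),
    timepoint = c(rep(c("pre", "post"), 5), rep(NA, n_qc)),
    sample_type = rep(c("study", "qc"), c(n_study, n_qc)),
    injection_order = 1:(n_study + n_qc))
  fm <- data.frame(feature_id = names(qc_vals), platform = "lcms-lipid")
  abundance_dataset(m, sm, fm)
}
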