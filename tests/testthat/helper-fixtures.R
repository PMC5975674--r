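# Small in-code fixtures shared across test files.

toy_matrix <- function(vals = matrix(1:6, 3, 2), features = NULL,
                       samples = NULL, platform = "toy", llq = NULL) {
  vals <- as.matrix(vals)
  rownames(vals) <- features %||% rownames(vals) %||%
    paste0("f", seq_len(nrow(vals)))
  colnames(vals) <- samples %||% colnames(vals) %||%
    paste0("s", seq_len(ncol(vals)))
  omics_matrix(vals, platform = platform, llq = llq)
}

toy_clinical <- function(n = 4, status = NULL, time = NULL, ids = NULL) {
  ids <- ids %||% paste0("s", seq_len(n))
  clinical_table(ids,
                 vital_status = status %||% rep_len(c(0, 1), n),
                 survival_time_days = time %||% seq(100, by = 50,
                                                    length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force log-rank (2 groups): O/E tally over event times
# with the hypergeometric variance.
brute_logrank_2g <- function(time, event, group) {
  g1 <- unique(group)[1L]
  O1 <- 0; E1 <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + n1 * d / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Scalar recomputation of the scaled-exponential kernel entry (i, j).
kernel_entry <- function(D, i, j, K, mu) {
  eps_i <- mean(sort(D[i, -i])[seq_len(K)])
  eps_j <- mean(sort(D[j, -j])[seq_len(K)])
  eps <- (eps_i + eps_j + D[i, j]) / 3
  exp(-D[i, j]^2 / (mu * eps))
}
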