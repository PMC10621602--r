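# fixtures built in code: small random three-level datasets

# random nested dataset with tie-free scores; guarantees both outcome
# classes when force_mixed
random_hier_data <- function(n, n_families = 3, max_persons = 2,
                             prevalence = 0.5, force_mixed = TRUE) {
  repeat {
    fam <- sample.int(n_families, n, replace = TRUE)
    per <- sample.int(max_persons, n, replace = TRUE)
    sub <- ave(seq_len(n), paste(fam, per), FUN = seq_along)
    ev <- rbinom(n, 1, prevalence)
    if (!force_mixed || (any(ev == 1) && any(ev == 0))) break
  }
  hier_data(data.frame(family = fam, person = per, subunit = sub,
                       score = runif(n), event = ev))
}

# the two-family worked example: theta3_hat = 3/4
toy_two_family <- function() {
  hier_data(data.frame(
    family  = c("f1", "f1", "f2", "f2"),
    person  = c("p1", "p1", "p1", "p1"),
    subunit = c("s1", "s2", "s1", "s2"),
    score   = c(0.1, 0.9, 0.5, 0.4),
    event   = c(0, 1, 0, 1)))
}

# literal enumeration of the extended Mann-Whitney sums (independent oracle
# for the rank-based counting)
brute_decomposition <- function(data) {
  fam <- match(data$family, unique(data$family))
  pid <- match(paste(fam, data$person), unique(paste(fam, data$person)))
  A <- B <- C <- nA <- nB <- nC <- 0
  for (a in which(data$event == 0)) {
    for (b in which(data$event == 1)) {
      conc <- data$score[a] < data$score[b]
      if (pid[a] == pid[b]) { nA <- nA + 1; A <- A + conc }
      else if (fam[a] == fam[b]) { nB <- nB + 1; B <- B + conc }
      else { nC <- nC + 1; C <- C + conc }
    }
  }
  list(A = A, B = B, C = C, nA = nA, nB = nB, nC = nC,
       theta_hat = (A + B + C) / (nA + nB + nC))
}
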