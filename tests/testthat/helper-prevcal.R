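# Shared fixtures and independent oracles for the test suite.
#
# The oracles below recompute metrics with plain arithmetic on the four
# counts, independently of the package's metric registry and of the
# closed-form (sen, spe, pre) expressions, so closed-form vs count-based
# agreement is a genuine dual-route check.

# the applicability-domain split: full test set and in-domain subset
profile_full <- function() performance_profile(0.680, 0.850, 0.600, 2000)
profile_in_domain <- function() performance_profile(0.710, 0.890, 0.900, 1000)

# random *integer* confusion matrix with both classes present
random_count_matrix <- function() {
  repeat {
    cells <- stats::rpois(4, lambda = stats::runif(4, 1, 200))
    if (cells[1] + cells[2] > 0 && cells[3] + cells[4] > 0) {
      return(confusion_matrix(cells[1], cells[2], cells[3], cells[4]))
    }
  }
}

# interior random profile, away from the undefined edges
random_interior_profile <- function() {
  random_profile(sen_range = c(0.01, 0.99), spe_range = c(0.01, 0.99),
                 pre_range = c(0.01, 0.99))
}

oracle_mcc <- function(cm) {
  with(cm, (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

oracle_accuracy <- function(cm) {
  with(cm, (tp + tn) / (tp + fn + fp + tn))
}

# kappa via the observed-vs-expected-agreement formulation
oracle_kappa <- function(cm) {
  n <- with(cm, tp + fn + fp + tn)
  po <- with(cm, (tp + tn) / n)
  pe <- with(cm, ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2)
  (po - pe) / (1 - pe)
}
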