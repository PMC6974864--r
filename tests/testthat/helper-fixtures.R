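# Shared fixtures: random strictly positive tables, toy rosters, and
# the published model-selection figures used as hold-out checks.

# strictly positive random capture-history table
random_table <- function(seed, min_cell = 50, max_cell = 5000) {
  cells <- recap3:::with_seed(seed, {
    round(stats::runif(7, min_cell, max_cell))
  })
  as_incomplete_table(setNames(cells,
                               c("n100", "n010", "n001", "n110",
                                 "n101", "n011", "n111")))
}

# minimal roster rows keyed by council code
toy_roster <- function(codes, ids = NA, names = NA, surnames = NA) {
  n <- length(codes)
  data.frame(
    source = rep("A", n),
    council_code = rep_len(codes, n),
    national_id = rep_len(ids, n),
    name = rep_len(names, n),
    surname = rep_len(surnames, n),
    sex = rep_len("male", n), age = rep_len(40, n),
    sector = rep_len("public", n), province = rep_len("p01", n),
    stringsAsFactors = FALSE
  )
}

# Published model-selection table of the three-list physician study:
# X (unobserved-cell estimate), G2, AIC per model, in this package's
# interaction labelling. Used as hold-out values, never as inputs to
# the recovery system beyond the seven X values of the dependent models.
published_table2 <- function() {
  data.frame(
    model = c("A/B/C", "AC", "BC", "AB",
              "AC/BC", "AB/AC", "AB/BC", "AB/AC/BC"),
    x = c(16353.43, 10053.04, 16553.54, 25846.32,
          9115.104, 16103.76, 32198.57, 21428.8),
    n = c(48552.43, 42254.04, 48754.54, 58047.32,
          41316.1, 48304.76, 64399.57, 53629.8),
    df = c(4, 5, 5, 5, 6, 6, 6, 7),
    g2 = c(1617.56, 432.50, 1614.71, 317.41,
           350.64, 53.88, 83.11, 0.01),
    aic = c(1695.44, 512.38, 1694.59, 397.28,
            423.52, 135.75, 164.99, 83.89),
    stringsAsFactors = FALSE
  )
}
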