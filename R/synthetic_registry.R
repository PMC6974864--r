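# Synthetic registry generator: ground-truth populations and three
# corrupted rosters whose overlap structure follows the same log-linear
# capture model the analysis fits.

# Default capture coefficients. These reproduce the dependence structure
# of a three-list physician-registry study with moderately sized lists,
# strong positive A-B dependence, and about 60% of the population
# appearing on at least one list (P(000) ~ 0.40).
.DEFAULT_LAMBDA_MAIN <- c(A = -0.551, B = -1.814, C = -1.197)
.DEFAULT_LAMBDA_PAIR <- c(AB = 0.855, AC = -0.407, BC = 0.286)

#' Ground truth for a synthetic three-list capture study
#'
#' Builds the generating model: cell probabilities over the eight capture
#' patterns \{000, 100, 010, 001, 110, 101, 011, 111\} (bit order A, B, C)
#' from a log-linear predictor with three main effects and three pairwise
#' interaction coefficients,
#' \deqn{\eta(a,b,c) = \lambda_A a + \lambda_B b + \lambda_C c +
#'       \lambda_{AB} ab + \lambda_{AC} ac + \lambda_{BC} bc,}
#' with cell 000 as reference (\eqn{\eta = 0}) and probabilities the
#' softmax of \eqn{\eta}. A zero pairwise coefficient means the two lists
#' capture independently; positive means individuals on one list are
#' over-represented on the other.
#'
#' @param lambda_main numeric length-3, main-effect coefficients
#'   \eqn{(\lambda_A, \lambda_B, \lambda_C)}.
#' @param lambda_pair numeric length-3, pairwise coefficients
#'   \eqn{(\lambda_{AB}, \lambda_{AC}, \lambda_{BC})}.
#' @param population_size true total population N (integer, at least 1).
#' @param seed integer seed used by [sample_histories()].
#' @return An object of class `synthetic_truth`: list with
#'   `population_size`, `lambda_main`, `lambda_pair`, `cell_probs`
#'   (named, in full pattern order, summing to 1) and `seed`.
#' @examples
#' truth <- build_truth(population_size = 8000, seed = 1)
#' truth$cell_probs
#' @export
build_truth <- function(lambda_main = .DEFAULT_LAMBDA_MAIN,
                        lambda_pair = .DEFAULT_LAMBDA_PAIR,
                        population_size,
                        seed = 1L) {
  lambda_main <- as.numeric(lambda_main)
  lambda_pair <- as.numeric(lambda_pair)
  if (length(lambda_main) != 3 || length(lambda_pair) != 3) {
    stop("lambda_main and lambda_pair must each have length 3")
  }
  if (any(!is.finite(c(lambda_main, lambda_pair)))) {
    stop("capture coefficients must be finite")
  }
  population_size <- as.integer(population_size)
  if (is.na(population_size) || population_size < 1) {
    stop("population_size must be a positive integer")
  }
  structure(
    list(
      population_size = population_size,
      lambda_main = setNames(lambda_main, c("A", "B", "C")),
      lambda_pair = setNames(lambda_pair, c("AB", "AC", "BC")),
      cell_probs = capture_cell_probs(lambda_main, lambda_pair),
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' Capture-pattern probabilities of a log-linear model
#'
#' @inheritParams build_truth
#' @return Named probabilities over the eight patterns, full order,
#'   summing to 1.
#' @export
capture_cell_probs <- function(lambda_main, lambda_pair) {
  bits <- .pattern_bits()
  eta <- bits %*% lambda_main +
    bits[, "A"] * bits[, "B"] * lambda_pair[1] +
    bits[, "A"] * bits[, "C"] * lambda_pair[2] +
    bits[, "B"] * bits[, "C"] * lambda_pair[3]
  # softmax; eta(000) = 0 by construction
  w <- exp(drop(eta))
  setNames(w / sum(w), .PATTERNS_FULL)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic capture truth: N =", x$population_size,
      " P(000) =", signif(x$cell_probs["000"], 4), "\n")
  print(signif(x$cell_probs, 4))
  invisible(x)
}

#' Draw capture histories from a synthetic truth
#'
#' Samples `population_size` individuals from the multinomial over the
#' eight capture patterns, using the seed stored in `truth`. Individuals
#' with pattern 000 are kept in the output (they are part of the true
#' population) but will appear in no roster.
#'
#' @param truth a [build_truth()] object.
#' @return Data frame with columns `person_id` and `pattern`
#'   (three-character bit string, order A, B, C).
#' @export
sample_histories <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  counts <- with_seed(truth$seed, {
    drop(stats::rmultinom(1, truth$population_size, truth$cell_probs))
  })
  data.frame(
    person_id = seq_len(truth$population_size),
    pattern = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
}

#' Corruption settings for synthetic rosters
#'
#' Controls the identifier damage applied when capture histories are
#' rendered as roster files: blanked registry (council) codes, blanked
#' national IDs, within-source duplicate rows, and misspelt names.
#' All rates are per-record probabilities in \[0, 1\].
#'
#' @param p_missing_council_code probability a roster row loses its
#'   council code (the primary linkage key).
#' @param p_missing_national_id probability a row loses its national ID.
#' @param p_within_source_duplicate probability a row is duplicated
#'   within its own roster.
#' @param name_variant_rate probability the given name has two adjacent
#'   characters transposed (a typo the exact-match cascade cannot heal).
#' @param seed integer seed driving all corruption draws.
#' @return An object of class `corruption_config`.
#' @export
corruption_config <- function(p_missing_council_code = 0.10,
                              p_missing_national_id = 0.05,
                              p_within_source_duplicate = 0.02,
                              name_variant_rate = 0.05,
                              seed = 1L) {
  p <- c(p_missing_council_code, p_missing_national_id,
         p_within_source_duplicate, name_variant_rate)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("all corruption probabilities must lie in [0, 1]")
  }
  structure(
    list(
      p_missing_council_code = p_missing_council_code,
      p_missing_national_id = p_missing_national_id,
      p_within_source_duplicate = p_within_source_duplicate,
      name_variant_rate = name_variant_rate,
      seed = as.integer(seed)
    ),
    class = "corruption_config"
  )
}

# Deterministic synthetic identifiers. Both tokens are zero-padded
# renderings of person_id (different widths), so a person is recoverable
# from either token when measuring linkage accuracy.
.council_code_of <- function(person_id) sprintf("%06d", person_id)
.national_id_of <- function(person_id) sprintf("%010d", person_id)

.NAME_POOL <- c("arman", "bahar", "dari", "elnaz", "farid", "golnar",
                "hamid", "kian", "leila", "majid", "nika", "omid",
                "parisa", "reza", "sara", "taraneh", "vahid", "yasmin")
.SURNAME_POOL <- c("ahmadi", "bagheri", "davari", "esfahani", "fallah",
                   "ghasemi", "hashemi", "jafari", "karimi", "moradi",
                   "nazari", "rahimi", "sadeghi", "tehrani", "zamani")
.PROVINCES <- paste0("province", sprintf("%02d", 1:31))

# Swap two adjacent characters (positions k, k+1) of a token.
.transpose_chars <- function(x, k) {
  ch <- strsplit(x, "")[[1]]
  if (length(ch) < 2) return(x)
  k <- min(k, length(ch) - 1)
  tmp <- ch[k]
  ch[k] <- ch[k + 1]
  ch[k + 1] <- tmp
  paste(ch, collapse = "")
}

#' Sample person-level attributes for a synthetic population
#'
#' Attributes carry no weight in the capture model; they make the rosters
#' look like registry extracts (sex, age, sector, province) and give
#' every person a name that the name-tier of the linkage cascade can use.
#' Names are ASCII tokens suffixed with the person id so that name keys
#' are unique in expectation.
#'
#' @param n number of persons.
#' @param seed integer seed.
#' @return Data frame with one row per person: `person_id`, `name`,
#'   `surname`, `sex`, `age`, `sector`, `province`.
#' @export
sample_attributes <- function(n, seed = 1L) {
  with_seed(seed, {
    data.frame(
      person_id = seq_len(n),
      name = paste0(sample(.NAME_POOL, n, replace = TRUE), seq_len(n)),
      surname = sample(.SURNAME_POOL, n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.54, 0.46)),
      age = pmin(pmax(round(stats::rnorm(n, 42, 10)), 25), 70),
      sector = sample(c("public", "private"), n, replace = TRUE,
                      prob = c(0.69, 0.31)),
      province = sample(.PROVINCES, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Render capture histories as three corrupted roster CSV files
#'
#' Every person whose pattern has the bit for a source set contributes at
#' least one row to that source's roster. Corruption then blanks council
#' codes and national IDs, injects within-source duplicate rows, and
#' transposes name characters, at the configured per-record rates. A
#' truth sidecar (`person_id,pattern`) is written beside the rosters so
#' linkage accuracy is measurable.
#'
#' Output is deterministic given `histories`, `attributes` and the
#' corruption seed: reruns produce byte-identical files.
#'
#' @param histories data frame from [sample_histories()].
#' @param attributes data frame from [sample_attributes()] (built
#'   automatically when `NULL`, seeded from `corruption$seed`).
#' @param corruption a [corruption_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `roster_paths` (named A, B, C),
#'   `sidecar_path`, and `rosters` (the written data frames).
#' @export
corrupt_and_write <- function(histories, attributes = NULL,
                              corruption = corruption_config(),
                              dir) {
  stopifnot(inherits(corruption, "corruption_config"))
  if (nrow(histories) == 0) stop("histories must be non-empty")
  if (is.null(attributes)) {
    attributes <- sample_attributes(max(histories$person_id),
                                    seed = corruption$seed)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  bits <- .pattern_bits()
  rosters <- with_seed(corruption$seed, {
    lapply(setNames(c("A", "B", "C"), c("A", "B", "C")), function(src) {
      keep <- bits[histories$pattern, src] == 1
      ids <- histories$person_id[keep]
      at <- attributes[match(ids, attributes$person_id), ]
      df <- data.frame(
        source = rep(src, length(ids)),
        council_code = .council_code_of(ids),
        national_id = .national_id_of(ids),
        name = at$name,
        surname = at$surname,
        sex = at$sex,
        age = at$age,
        sector = at$sector,
        province = at$province,
        stringsAsFactors = FALSE
      )
      n <- nrow(df)
      if (n > 0) {
        blank_code <- stats::runif(n) < corruption$p_missing_council_code
        blank_id <- stats::runif(n) < corruption$p_missing_national_id
        typo <- stats::runif(n) < corruption$name_variant_rate
        typo_pos <- sample.int(4, n, replace = TRUE)
        dup <- stats::runif(n) < corruption$p_within_source_duplicate
        df$council_code[blank_code] <- ""
        df$national_id[blank_id] <- ""
        if (any(typo)) {
          df$name[typo] <- mapply(.transpose_chars, df$name[typo],
                                  typo_pos[typo], USE.NAMES = FALSE)
        }
        if (any(dup)) {
          df <- rbind(df, df[dup, , drop = FALSE])
        }
      }
      rownames(df) <- NULL
      df
    })
  })

  roster_paths <- vapply(names(rosters), function(src) {
    p <- file.path(dir, paste0("roster_", src, ".csv"))
    utils::write.csv(rosters[[src]], p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))

  sidecar_path <- file.path(dir, "truth_sidecar.csv")
  utils::write.csv(histories[, c("person_id", "pattern")], sidecar_path,
                   row.names = FALSE, quote = FALSE)

  invisible(list(roster_paths = roster_paths,
                 sidecar_path = sidecar_path,
                 rosters = rosters))
}

#' Simulate a complete synthetic registry study
#'
#' Convenience wrapper: draws capture histories from `truth`, samples
#' attributes, and writes the three corrupted rosters plus the truth
#' sidecar to `dir`.
#'
#' @param truth a [build_truth()] object.
#' @param corruption a [corruption_config()].
#' @param dir output directory.
#' @return The [corrupt_and_write()] result, plus elements `truth` and
#'   `histories`.
#' @export
simulate_registry <- function(truth, corruption = corruption_config(),
                              dir) {
  histories <- sample_histories(truth)
  out <- corrupt_and_write(histories,
                           attributes = sample_attributes(
                             truth$population_size,
                             seed = corruption$seed),
                           corruption = corruption, dir = dir)
  out$truth <- truth
  out$histories <- histories
  invisible(out)
}
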