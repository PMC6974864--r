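# Deterministic record linkage: normalization, within-source
# deduplication, reference enrichment, and cross-source tabulation into
# the incomplete 2^3 capture-history table.
#
# Linkage is an exact-match cascade over three key tiers, in precedence
# order: council_code > national_id > name_surname. A lower tier is only
# consulted for records the higher tiers could not key, so two records
# distinguished by distinct council codes are never merged by a shared
# national ID (the conflict is logged instead). No fuzzy matching.

.KEY_SEP <- "\x1f" # reserved separator inside the name_surname key

.normalize_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- NA_character_
  x
}

#' Normalize a roster for linkage
#'
#' Strips whitespace and case-folds the identifier fields, maps empty
#' strings to missing, and derives the three linkage keys: `key_code`
#' (council code), `key_id` (national ID) and `key_name`
#' (name and surname joined by a reserved separator, present only when
#' both are). Leading zeros in identifier tokens are preserved. Records
#' with no usable key are flagged `unlinkable`.
#'
#' @param roster data frame with columns `council_code`, `national_id`,
#'   `name`, `surname` (other columns pass through).
#' @return The roster with columns `key_code`, `key_id`, `key_name`,
#'   `unlinkable` appended.
#' @export
normalize_roster <- function(roster) {
  roster$key_code <- .normalize_token(roster$council_code)
  roster$key_id <- .normalize_token(roster$national_id)
  nm <- .normalize_token(roster$name)
  sn <- .normalize_token(roster$surname)
  roster$key_name <- ifelse(is.na(nm) | is.na(sn), NA_character_,
                            paste(nm, sn, sep = .KEY_SEP))
  roster$unlinkable <- is.na(roster$key_code) & is.na(roster$key_id) &
    is.na(roster$key_name)
  roster
}

# Assign an entity id to every row of a normalized record set.
#
# Tier 1: rows sharing a council code form one entity.
# Tier 2: code-less rows attach by national ID to the unique entity
#         already holding that ID, or form a new entity per distinct ID;
#         an ID claimed by >= 2 code-distinct entities is a cross-tier
#         conflict: the rows form their own entity (code wins) and the
#         conflict is logged. This keeps linkage order-invariant.
# Tier 3: as tier 2, on the name_surname key, for rows with neither code
#         nor ID.
#
# Returns list(entity = integer (NA for unlinkable rows),
#              tier = resolving tier per row, audit = data frame).
.resolve_entities <- function(df) {
  n <- nrow(df)
  entity <- rep(NA_integer_, n)
  tier <- rep(NA_character_, n)
  audit <- list()
  log_event <- function(event, key_tier, key, detail) {
    audit[[length(audit) + 1]] <<- data.frame(
      event = event, tier = key_tier, key = key, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (n == 0) {
    return(list(entity = entity, tier = tier,
                audit = data.frame(event = character(), tier = character(),
                                   key = character(), detail = character())))
  }

  # tier 1: council code
  has_code <- !is.na(df$key_code)
  codes <- unique(df$key_code[has_code])
  entity[has_code] <- match(df$key_code[has_code], codes)
  tier[has_code] <- "council_code"
  next_id <- length(codes)

  attach_tier <- function(key_col, tier_name, pending) {
    keys <- df[[key_col]]
    use <- pending & !is.na(keys)
    if (!any(use)) return(invisible(NULL))
    # map key -> entities already assigned
    assigned <- !is.na(entity)
    known <- split(entity[assigned & !is.na(keys)],
                   keys[assigned & !is.na(keys)])
    for (k in unique(keys[use])) {
      rows <- which(use & keys == k)
      owners <- unique(known[[k]])
      if (length(owners) == 1) {
        entity[rows] <<- owners
      } else {
        if (length(owners) > 1) {
          log_event("conflict", tier_name, k,
                    sprintf("%s shared by %d code-distinct entities; kept separate",
                            tier_name, length(owners)))
        }
        next_id <<- next_id + 1L
        entity[rows] <<- next_id
      }
      tier[rows] <<- tier_name
    }
    invisible(NULL)
  }

  attach_tier("key_id", "national_id", is.na(entity) & !is.na(df$key_id))
  attach_tier("key_name", "name_surname",
              is.na(entity) & is.na(df$key_id) & !is.na(df$key_name))

  unlink_rows <- which(is.na(entity))
  for (r in unlink_rows) {
    log_event("unlinkable", NA_character_, NA_character_,
              sprintf("row %d has no usable key; excluded from tabulation", r))
  }

  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(event = character(), tier = character(),
               key = character(), detail = character())
  list(entity = entity, tier = tier, audit = audit)
}

#' Deduplicate a roster within one source
#'
#' Collapses rows that the key cascade identifies as the same person:
#' rows sharing a council code first, then (among code-less rows) rows
#' sharing a national ID, then rows sharing the name key. Each collapse
#' keeps the first-seen row. Merges are recorded in the `"audit"`
#' attribute of the result.
#'
#' @param roster a roster data frame (normalized automatically if the
#'   key columns are absent).
#' @return The deduplicated roster, with attributes `audit` (merge log)
#'   and `n_merged`.
#' @export
dedup_within <- function(roster) {
  if (is.null(roster$key_code)) roster <- normalize_roster(roster)
  if (nrow(roster) == 0) {
    attr(roster, "audit") <- data.frame(event = character(),
                                        tier = character(),
                                        key = character(),
                                        detail = character())
    attr(roster, "n_merged") <- 0L
    return(roster)
  }
  res <- .resolve_entities(roster)
  grp <- res$entity
  # unlinkable rows each stand alone
  grp[is.na(grp)] <- max(grp, 0L, na.rm = TRUE) + seq_len(sum(is.na(grp)))
  keep <- !duplicated(grp)
  merges <- res$audit
  dup_rows <- which(!keep)
  if (length(dup_rows)) {
    merges <- rbind(merges, data.frame(
      event = "merge",
      tier = res$tier[dup_rows],
      key = ifelse(is.na(res$tier[dup_rows]), NA_character_,
                   ifelse(res$tier[dup_rows] == "council_code",
                          roster$key_code[dup_rows],
                          ifelse(res$tier[dup_rows] == "national_id",
                                 roster$key_id[dup_rows],
                                 roster$key_name[dup_rows]))),
      detail = sprintf("row %d merged into first-seen row of its entity",
                       dup_rows),
      stringsAsFactors = FALSE))
  }
  out <- roster[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- merges
  attr(out, "n_merged") <- length(dup_rows)
  out
}

#' Fill missing council codes from a reference roster
#'
#' Looks up records whose council code is missing against a reference
#' table (e.g. the profession-wide graduate registry) by national ID,
#' then by name key. A code is filled only when the reference yields
#' exactly one candidate; ambiguous matches are left missing and logged.
#'
#' @param roster a (normalized) roster data frame.
#' @param reference data frame with columns `council_code`,
#'   `national_id`, `name`, `surname`.
#' @return The enriched roster, with attribute `enrich_log`.
#' @export
enrich_from_reference <- function(roster, reference) {
  required <- c("council_code", "national_id", "name", "surname")
  if (!all(required %in% names(reference))) {
    stop("reference must have columns ",
         paste(required, collapse = ", "))
  }
  if (is.null(roster$key_code)) roster <- normalize_roster(roster)
  reference <- normalize_roster(reference)
  reference <- reference[!is.na(reference$key_code), , drop = FALSE]

  lookup <- function(keys, ref_keys) {
    # returns fill codes (NA when 0 or >1 distinct candidates)
    vapply(keys, function(k) {
      if (is.na(k)) return(NA_character_)
      cand <- unique(reference$key_code[!is.na(ref_keys) & ref_keys == k])
      if (length(cand) == 1) cand else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  ambiguous <- function(keys, ref_keys) {
    vapply(keys, function(k) {
      if (is.na(k)) return(FALSE)
      length(unique(reference$key_code[!is.na(ref_keys) & ref_keys == k])) > 1
    }, logical(1), USE.NAMES = FALSE)
  }

  need <- is.na(roster$key_code)
  log <- list()
  if (any(need)) {
    fill <- lookup(roster$key_id[need], reference$key_id)
    amb <- ambiguous(roster$key_id[need], reference$key_id)
    still <- is.na(fill)
    fill2 <- lookup(roster$key_name[need][still], reference$key_name)
    amb2 <- ambiguous(roster$key_name[need][still], reference$key_name)
    fill[still] <- fill2
    amb[still] <- amb[still] | amb2
    rows <- which(need)
    filled <- !is.na(fill)
    roster$council_code[rows[filled]] <- fill[filled]
    roster$key_code[rows[filled]] <- fill[filled]
    roster$unlinkable[rows[filled]] <- FALSE
    if (any(amb & !filled)) {
      log <- list(data.frame(
        event = "ambiguous_reference",
        row = rows[amb & !filled],
        detail = "reference maps key to multiple council codes; left missing",
        stringsAsFactors = FALSE))
    }
  }
  attr(roster, "enrich_log") <- if (length(log)) log[[1]] else
    data.frame(event = character(), row = integer(), detail = character())
  roster
}

#' Tabulate three rosters into the incomplete capture-history table
#'
#' Unifies records across the three (deduplicated) rosters by the same
#' key cascade used within sources, then counts entities into the seven
#' observed capture-history cells by which sources they appear in.
#' Records with no usable key are excluded from tabulation with a
#' warning; merges and cross-tier conflicts are logged.
#'
#' @param roster_a,roster_b,roster_c deduplicated roster data frames for
#'   sources A, B, C (a `source` column, if absent, is set from the
#'   argument position).
#' @return An [incomplete_table()], with attributes `entities` (one row
#'   per resolved entity: flags, resolving tier, representative keys),
#'   `rows` (row-level assignment), `audit` (conflict/unlinkable log)
#'   and `n_unlinkable`.
#' @export
tabulate_rosters <- function(roster_a, roster_b, roster_c) {
  rosters <- list(A = roster_a, B = roster_b, C = roster_c)
  rosters <- lapply(names(rosters), function(src) {
    r <- rosters[[src]]
    if (nrow(r) > 0) r$source <- src else r$source <- character(0)
    if (is.null(r$key_code)) r <- normalize_roster(r)
    r[, c("source", "key_code", "key_id", "key_name", "unlinkable")]
  })
  all_rows <- do.call(rbind, rosters)

  if (nrow(all_rows) == 0) {
    tab <- as_incomplete_table(setNames(rep(0, 7), .CELL_NAMES))
    attr(tab, "entities") <- data.frame()
    attr(tab, "rows") <- all_rows
    attr(tab, "audit") <- data.frame(event = character(), tier = character(),
                                     key = character(), detail = character())
    attr(tab, "n_unlinkable") <- 0L
    return(tab)
  }

  res <- .resolve_entities(all_rows)
  n_unlinkable <- sum(is.na(res$entity))
  if (n_unlinkable > 0) {
    warning(n_unlinkable,
            " record(s) with no usable key excluded from tabulation")
  }
  keep <- !is.na(res$entity)
  ent <- res$entity[keep]
  src <- all_rows$source[keep]

  flags <- vapply(c("A", "B", "C"), function(s) {
    as.integer(tapply(src == s, ent, any))
  }, integer(length(unique(ent))))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1,
                                           dimnames = list(NULL, c("A", "B", "C")))
  pattern <- paste0(flags[, "A"], flags[, "B"], flags[, "C"])

  counts <- table(factor(pattern, levels = .PATTERNS_OBS))
  tab <- as_incomplete_table(setNames(as.numeric(counts),
                                      paste0("n", names(counts))))

  first_key <- function(col) {
    tapply(all_rows[[col]][keep], ent, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[1] else NA_character_
    })
  }
  entities <- data.frame(
    entity_id = sort(unique(ent)),
    in_A = flags[, "A"] == 1,
    in_B = flags[, "B"] == 1,
    in_C = flags[, "C"] == 1,
    pattern = pattern,
    resolution_tier = as.character(tapply(res$tier[keep], ent, `[`, 1)),
    council_code = as.character(first_key("key_code")),
    national_id = as.character(first_key("key_id")),
    n_rows = as.integer(tapply(ent, ent, length)),
    stringsAsFactors = FALSE
  )

  all_rows$entity <- res$entity
  attr(tab, "entities") <- entities
  attr(tab, "rows") <- all_rows
  attr(tab, "audit") <- res$audit
  attr(tab, "n_unlinkable") <- n_unlinkable
  tab
}

#' Measure linkage accuracy against a synthetic truth sidecar
#'
#' For synthetic rosters, identifier tokens encode the generating person
#' id, so each resolved entity can be traced back to the person it most
#' plausibly represents. A person counts as correctly resolved when
#' exactly one entity traces to them and that entity's capture pattern
#' equals the true pattern in the sidecar.
#'
#' @param table result of [tabulate_rosters()] on synthetic rosters.
#' @param sidecar data frame `person_id,pattern` written by
#'   [corrupt_and_write()] (or its file path).
#' @return Fraction of observed (pattern != 000) persons correctly
#'   resolved, in \[0, 1\].
#' @export
linkage_accuracy <- function(table, sidecar) {
  if (is.character(sidecar)) {
    sidecar <- utils::read.csv(sidecar, colClasses = c("integer", "character"))
  }
  entities <- attr(table, "entities")
  observed <- sidecar[sidecar$pattern != "000", , drop = FALSE]
  if (nrow(observed) == 0) return(NA_real_)

  person_of <- function(code, id) {
    p <- suppressWarnings(as.integer(code))
    p2 <- suppressWarnings(as.integer(id))
    if (!is.na(p)) p else p2
  }
  pid <- mapply(person_of, entities$council_code, entities$national_id,
                USE.NAMES = FALSE)

  correct <- 0L
  claims <- split(seq_len(nrow(entities)), pid)
  for (i in seq_len(nrow(observed))) {
    who <- claims[[as.character(observed$person_id[i])]]
    if (length(who) == 1 &&
        entities$pattern[who] == observed$pattern[i]) {
      correct <- correct + 1L
    }
  }
  correct / nrow(observed)
}
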