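#' Pedigree tables
#'
#' A pedigree is a tibble with one row per individual and columns `id`, `sire`,
#' `dam`, `sex`, `birth_year`, `death_year` and (optionally) `final_year`.
#' Unknown parents, sexes and death years are `NA`. The object carries a
#' `year_range` attribute derived from the birth years.
#'
#' @name pedigree
NULL

ped_required_cols <- c("id", "sire", "dam", "sex", "birth_year", "death_year")

new_pedigree <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "year_range") <- range(tbl$birth_year, na.rm = TRUE)
  class(tbl) <- unique(c("pedigree", class(tbl)))
  tbl
}

#' Coerce a data frame to a pedigree
#'
#' Column names are matched case-insensitively against `ID`, `SIRE`, `DAM`,
#' `SEX`, `BIRTH_YEAR`, `DEATH_YEAR` and optional `FINAL_YEAR` (a last-seen
#' year used for individuals whose death year is unknown). Extra columns are
#' preserved but ignored by all computations.
#'
#' Fatal structural defects (duplicated ids, parent ids that do not resolve to
#' a row, parent cycles) raise an error; all other invariant violations are
#' left for [validate_pedigree()] to report.
#'
#' @param df Data frame of individuals.
#' @param missing_code Character vector of cell values to treat as unknown, in
#'   addition to `NA` (default `"NA"` and `"0"`, the two common pedigree
#'   dialects).
#' @return A `pedigree` tibble.
#' @export
as_pedigree <- function(df, missing_code = c("NA", "0")) {
  df <- tibble::as_tibble(df)
  lower <- tolower(names(df))
  map <- c(
    id = "id", sire = "sire", dam = "dam", sex = "sex",
    birth_year = "birth_year", death_year = "death_year",
    final_year = "final_year"
  )
  for (target in names(map)) {
    hit <- which(lower == target)
    if (length(hit) == 1L) names(df)[hit] <- target
  }
  missing_req <- setdiff(c("id", "sire", "dam", "birth_year"), names(df))
  if (length(missing_req) > 0) {
    abort(paste0("Pedigree is missing required column(s): ",
                 paste(toupper(missing_req), collapse = ", ")))
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  if (!"death_year" %in% names(df)) df$death_year <- NA_integer_

  blank <- function(x) {
    x <- as.character(x)
    x[x %in% missing_code | x == ""] <- NA_character_
    x
  }
  df$id <- as.character(df$id)
  df$sire <- blank(df$sire)
  df$dam <- blank(df$dam)
  df$sex <- tolower(blank(df$sex))
  bad_sex <- setdiff(unique(na.omit(df$sex)), c("male", "female", "m", "f"))
  if (length(bad_sex) > 0) {
    abort(paste0("Unrecognised SEX value(s): ", paste(bad_sex, collapse = ", ")))
  }
  df$sex <- dplyr::recode(df$sex, m = "male", f = "female")
  df$birth_year <- as.integer(blank(df$birth_year))
  df$death_year <- as.integer(blank(df$death_year))
  if ("final_year" %in% names(df)) {
    df$final_year <- as.integer(blank(df$final_year))
  }

  if (any(is.na(df$id) | df$id == "")) abort("Every individual needs a non-empty ID.")
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate individual ID(s): ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(df$birth_year))) {
    abort(paste0("Missing BIRTH_YEAR for: ",
                 paste(df$id[is.na(df$birth_year)], collapse = ", ")))
  }
  unresolved <- setdiff(c(na.omit(df$sire), na.omit(df$dam)), df$id)
  if (length(unresolved) > 0) {
    abort(paste0("Parent ID(s) not present in the pedigree: ",
                 paste(unresolved, collapse = ", ")))
  }

  ped <- new_pedigree(df)
  cyc <- find_parent_cycle(ped)
  if (!is.null(cyc)) {
    abort(paste0("Pedigree contains a parent cycle: ",
                 paste(cyc, collapse = " -> ")))
  }
  ped
}

#' Read a pedigree from a tab-separated file
#'
#' Expects a header with columns `ID`, `SIRE`, `DAM` and `BIRTH_YEAR`;
#' `SEX`, `DEATH_YEAR` and `FINAL_YEAR` are optional. See [as_pedigree()] for
#' the missing-value and validation conventions.
#'
#' @param path Path to a TSV file.
#' @inheritParams as_pedigree
#' @return A `pedigree` tibble.
#' @export
read_pedigree <- function(path, missing_code = c("NA", "0")) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  as_pedigree(df, missing_code = missing_code)
}

#' Write a pedigree in the same TSV dialect read_pedigree() accepts
#'
#' @param ped A `pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- tibble::tibble(
    ID = ped$id, SIRE = ped$sire, DAM = ped$dam, SEX = ped$sex,
    BIRTH_YEAR = ped$birth_year, DEATH_YEAR = ped$death_year
  )
  if ("final_year" %in% names(ped)) out$FINAL_YEAR <- ped$final_year
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

# Locate one parent cycle (vector of ids, first == last), or NULL if acyclic.
find_parent_cycle <- function(ped) {
  idx <- match_parents(ped)
  n <- nrow(ped)
  state <- integer(n) # 0 unvisited, 1 on current path, 2 done
  result <- NULL
  path <- integer(0)
  visit <- function(i) {
    if (!is.null(result)) return(invisible())
    state[i] <<- 1L
    path <<- c(path, i)
    for (p in c(idx$sire[i], idx$dam[i])) {
      if (is.na(p) || !is.null(result)) next
      if (state[p] == 1L) {
        result <<- ped$id[c(path[which(path == p)[1]:length(path)], p)]
      } else if (state[p] == 0L) {
        visit(p)
      }
    }
    path <<- path[-length(path)]
    state[i] <<- 2L
    invisible()
  }
  for (s in seq_len(n)) {
    if (state[s] == 0L && is.null(result)) visit(s)
  }
  result
}

match_parents <- function(ped) {
  list(
    sire = match(ped$sire, ped$id),
    dam = match(ped$dam, ped$id)
  )
}

#' Check pedigree invariants
#'
#' Reports (rather than raises) violations of the pedigree invariants:
#' individuals who are their own parent, death before birth, parents born in
#' the same year as or after their offspring, sires that are not male, dams
#' that are not female, and parent cycles.
#'
#' @param ped A `pedigree`.
#' @return A tibble with columns `id`, `rule` and `detail`; zero rows when all
#'   invariants hold.
#' @export
validate_pedigree <- function(ped) {
  v <- list()
  add <- function(id, rule, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(id = id, rule = rule, detail = detail)
  }
  idx <- match_parents(ped)

  self <- which(!is.na(ped$sire) & ped$sire == ped$id |
                  !is.na(ped$dam) & ped$dam == ped$id)
  for (i in self) add(ped$id[i], "self_parent", "individual recorded as its own parent")

  bad_life <- which(!is.na(ped$death_year) & ped$death_year < ped$birth_year)
  for (i in bad_life) {
    add(ped$id[i], "death_before_birth",
        sprintf("death_year %d precedes birth_year %d", ped$death_year[i], ped$birth_year[i]))
  }

  for (role in c("sire", "dam")) {
    p <- idx[[role]]
    known <- which(!is.na(p))
    late <- known[ped$birth_year[p[known]] >= ped$birth_year[known]]
    for (i in late) {
      add(ped$id[i], "parent_not_older",
          sprintf("%s %s born %d, offspring born %d", role, ped$id[p[i]],
                  ped$birth_year[p[i]], ped$birth_year[i]))
    }
    want <- if (role == "sire") "male" else "female"
    wrong <- known[!is.na(ped$sex[p[known]]) & ped$sex[p[known]] != want]
    for (i in unique(p[wrong])) {
      add(ped$id[i], paste0(role, "_sex"),
          sprintf("recorded as %s of %s but sex is %s", role,
                  paste(ped$id[wrong[p[wrong] == i]], collapse = ","), ped$sex[i]))
    }
  }

  cyc <- find_parent_cycle(ped)
  if (!is.null(cyc)) {
    add(cyc[1], "cycle", paste0("parent cycle: ", paste(cyc, collapse = " -> ")))
  }

  if (length(v) == 0) {
    tibble::tibble(id = character(), rule = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Topological order of a pedigree
#'
#' Returns the individual ids ordered so that both known parents of every
#' individual appear before it; ties are broken by `(birth_year, id)` so the
#' order is deterministic. This is the processing order used by the gene-drop.
#'
#' @param ped A `pedigree`.
#' @return Character vector of ids.
#' @export
topological_order <- function(ped) {
  n <- nrow(ped)
  ord <- order(ped$birth_year, ped$id)
  idx <- match_parents(ped)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  ok <- all(is.na(idx$sire) | pos[idx$sire] < pos[seq_len(n)]) &&
    all(is.na(idx$dam) | pos[idx$dam] < pos[seq_len(n)])
  if (ok) {
    return(ped$id[ord])
  }
  # Fall back to Kahn's algorithm with ordered extraction for pedigrees whose
  # birth years do not already respect the parent links.
  cyc <- find_parent_cycle(ped)
  if (!is.null(cyc)) {
    abort(paste0("Pedigree contains a parent cycle: ", paste(cyc, collapse = " -> ")))
  }
  indeg <- (!is.na(idx$sire)) + (!is.na(idx$dam))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(idx$sire[i], idx$dam[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  key <- order(ped$birth_year, ped$id)
  rank <- integer(n)
  rank[key] <- seq_len(n)
  ready <- which(indeg == 0L)
  out <- integer(0)
  while (length(ready) > 0) {
    i <- ready[which.min(rank[ready])]
    ready <- setdiff(ready, i)
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  ped$id[out]
}

#' Birth cohort of a given year
#'
#' @param ped A `pedigree`.
#' @param year Calendar year.
#' @return Character vector of ids born in `year` (possibly empty).
#' @export
birth_cohort <- function(ped, year) {
  ped$id[ped$birth_year == year]
}

#' Individuals alive (standing population) in a given year
#'
#' The life interval is inclusive on both ends: an individual dying in year
#' `y` is still part of the standing population of year `y`. Individuals with
#' an unknown death year contribute only to their birth year, unless a
#' `final_year` (last seen) column extends them.
#'
#' @param ped A `pedigree`.
#' @param year Calendar year.
#' @return Character vector of ids alive in `year`.
#' @export
alive_in_year <- function(ped, year) {
  last <- effective_final_year(ped)
  ped$id[ped$birth_year <= year & year <= last]
}

effective_final_year <- function(ped) {
  last <- ped$death_year
  if ("final_year" %in% names(ped)) {
    last[is.na(last)] <- ped$final_year[is.na(last)]
  }
  last[is.na(last)] <- ped$birth_year[is.na(last)]
  last
}

#' @export
print.pedigree <- function(x, ...) {
  yr <- attr(x, "year_range")
  cat(sprintf("# A pedigree: %d individuals, birth years %d-%d\n",
              nrow(x), yr[1], yr[2]))
  NextMethod()
}
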