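#' Construct a pedigree from a data frame of individual records
#'
#' A pedigree holds one record per individual: identifier, parent links, sex,
#' dates, birth program (region), origin (wild or captive born), hybrid flag
#' and species label. Unknown parents are stored as `NA` and treated, for all
#' derived quantities, as unique unrelated wild founders (the usual
#' "set unknown parents to wild" studbook convention).
#'
#' @param records data frame with columns `id`, `sire`, `dam`, `sex`,
#'   `birth_date`, `death_date`, `birth_program`, `origin`, `hybrid`,
#'   `species`, and optionally `release_date`. Parent columns may use `NA`,
#'   `""` or `"UNKNOWN"` for unknown parents; `death_date` may use `NA`, `""`
#'   or `"ALIVE"` for living individuals.
#' @param current_date reference date of the studbook; defaults to the latest
#'   birth or death date on file.
#' @param check if `TRUE` (default), referential integrity and basic field
#'   validity are enforced with hard errors. Structural invariants that
#'   [validate_pedigree()] is designed to report (cycles, parent/offspring
#'   chronology) are *not* checked here.
#' @return An object of class `pedigree`: a list with elements `records`
#'   (normalised data frame) and `current_date` (a `Date`).
#' @seealso [read_studbook()], [validate_pedigree()]
#' @export
as_pedigree <- function(records, current_date = NULL, check = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("id", "sire", "dam", "sex", "birth_date", "death_date",
                "birth_program", "origin", "hybrid", "species")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))

  records$id <- as.character(records$id)
  records$sire <- normalize_parent(records$sire)
  records$dam <- normalize_parent(records$dam)
  records$sex <- normalize_sex(records$sex)
  records$birth_date <- parse_dates(records$birth_date, "birth_date")
  records$death_date <- parse_dates(records$death_date, "death_date",
                                    allow_missing = TRUE)
  records$birth_program <- ifelse(is.na(records$birth_program) |
                                    records$birth_program == "",
                                  "unknown", as.character(records$birth_program))
  records$origin <- normalize_origin(records$origin)
  records$hybrid <- normalize_flag(records$hybrid)
  records$species <- as.character(records$species)
  if ("release_date" %in% names(records))
    records$release_date <- parse_dates(records$release_date, "release_date",
                                        allow_missing = TRUE)

  if (check) {
    if (any(is.na(records$id) | records$id == ""))
      stopf("empty individual id at row(s) %s",
            paste(which(is.na(records$id) | records$id == ""), collapse = ", "))
    dup <- unique(records$id[duplicated(records$id)])
    if (length(dup))
      stopf("duplicate individual id(s): %s", paste(dup, collapse = ", "))
    if (anyNA(records$birth_date))
      stopf("missing birth_date at row(s) %s",
            paste(which(is.na(records$birth_date)), collapse = ", "))
    for (col in c("sire", "dam")) {
      dangling <- setdiff(records[[col]][!is.na(records[[col]])], records$id)
      if (length(dangling))
        stopf("%s id(s) not present in the studbook: %s", col,
              paste(unique(dangling), collapse = ", "))
    }
    bad <- which(!is.na(records$death_date) &
                   records$death_date < records$birth_date)
    if (length(bad))
      stopf("death_date precedes birth_date at row(s) %s (id %s)",
            paste(bad, collapse = ", "),
            paste(records$id[bad], collapse = ", "))
  }

  if (is.null(current_date)) {
    current_date <- suppressWarnings(
      max(c(records$birth_date, records$death_date), na.rm = TRUE))
  }
  structure(list(records = records, current_date = as.Date(current_date)),
            class = "pedigree")
}

#' Read a studbook CSV file
#'
#' The studbook dialect is a UTF-8, comma-separated table with header columns
#' `id`, `sire`, `dam`, `sex`, `birth_date`, `death_date`, `birth_program`,
#' `origin`, `hybrid`, `species` (and optionally `release_date`). Dates are
#' ISO-8601 (`YYYY-MM-DD`); unknown parents are `UNKNOWN` or empty; living
#' individuals have an empty or `ALIVE` death date.
#'
#' @param path path to the CSV file.
#' @param species_label optional species label to assign when the file lacks a
#'   `species` column (single-species studbook exports).
#' @return A [pedigree][as_pedigree] object.
#' @export
read_studbook <- function(path, species_label = NULL) {
  if (!file.exists(path)) stopf("studbook file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  strip.white = TRUE)
  if (!is.null(species_label) && !"species" %in% names(raw))
    raw$species <- species_label
  as_pedigree(raw, check = TRUE)
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | toupper(x) == "UNKNOWN" | toupper(x) == "NA"] <- NA
  x
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  out
}

normalize_origin <- function(x) {
  x <- tolower(as.character(x))
  bad <- !x %in% c("wild", "captive")
  if (any(bad))
    stopf("origin must be 'wild' or 'captive' (row(s) %s)",
          paste(which(bad), collapse = ", "))
  x
}

normalize_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(as.character(x))
  x %in% c("true", "t", "1", "yes", "y")
}

parse_dates <- function(x, field, allow_missing = FALSE) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  missing <- is.na(x) | x == "" | toupper(x) == "ALIVE" | toupper(x) == "NA"
  out <- rep(as.Date(NA), length(x))
  idx <- which(!missing)
  if (length(idx)) {
    parsed <- as.Date(x[idx], format = "%Y-%m-%d")
    bad <- idx[is.na(parsed)]
    if (length(bad))
      stopf("unparseable %s at row(s) %s: %s", field,
            paste(bad, collapse = ", "),
            paste(unique(x[bad]), collapse = ", "))
    out[idx] <- parsed
  }
  if (!allow_missing && any(missing) && field == "birth_date")
    stopf("missing %s at row(s) %s", field, paste(which(missing), collapse = ", "))
  out
}

#' @export
print.pedigree <- function(x, ...) {
  r <- x$records
  cat(sprintf("<pedigree> %d individuals, %d species, current date %s\n",
              nrow(r), length(unique(r$species)), format(x$current_date)))
  cat(sprintf("  wild-born: %d; unknown sire: %d; unknown dam: %d; hybrids: %d\n",
              sum(r$origin == "wild"), sum(is.na(r$sire)), sum(is.na(r$dam)),
              sum(r$hybrid)))
  invisible(x)
}

# ---- internal accessors -----------------------------------------------------

ped_ids <- function(p) p$records$id

ped_index <- function(p) setNames(seq_len(nrow(p$records)), p$records$id)

# Integer parent indices (NA for unknown). With `wild_as_founder` (the
# default, mirroring the convention that wild-born animals are pedigree
# founders), recorded parents of wild-born individuals are dropped so that
# their ancestry contributes nothing to f, kinship or generations.
parent_indices <- function(p, wild_as_founder = TRUE) {
  idx <- ped_index(p)
  r <- p$records
  si <- unname(idx[match(r$sire, names(idx))])
  di <- unname(idx[match(r$dam, names(idx))])
  if (wild_as_founder) {
    si[r$origin == "wild"] <- NA_integer_
    di[r$origin == "wild"] <- NA_integer_
  }
  list(sire = si, dam = di)
}

# Topological depth over the given parent maps: founders 0, otherwise
# 1 + max(parent depth). Returns NA for individuals on (or downstream of) a
# parent-link cycle.
topo_depth <- function(sire, dam, n) {
  depth <- rep(NA_real_, n)
  depth[is.na(sire) & is.na(dam)] <- 0
  repeat {
    ds <- ifelse(is.na(sire), -1, depth[ifelse(is.na(sire), 1L, sire)])
    dd <- ifelse(is.na(dam), -1, depth[ifelse(is.na(dam), 1L, dam)])
    cand <- pmax(ds, dd) + 1
    newly <- which(is.na(depth) & !is.na(cand))
    if (!length(newly)) break
    depth[newly] <- cand[newly]
  }
  depth
}

#' Check pedigree structural invariants
#'
#' Scans a pedigree for violations of its structural invariants and returns
#' them as a table instead of raising errors: unresolved parent links,
#' parent-link cycles, parents born on or after an offspring's birth date, and
#' death before birth.
#'
#' @param p a [pedigree][as_pedigree].
#' @return A data frame with columns `rule`, `ids` and `detail`; zero rows if
#'   every invariant holds.
#' @export
validate_pedigree <- function(p) {
  r <- p$records
  v <- list()
  add <- function(rule, ids, detail)
    v[[length(v) + 1L]] <<- data.frame(rule = rule,
                                       ids = paste(ids, collapse = ","),
                                       detail = detail,
                                       stringsAsFactors = FALSE)

  dup <- unique(r$id[duplicated(r$id)])
  if (length(dup)) add("unique_id", dup, "duplicate individual id")

  idx <- ped_index(p)
  for (col in c("sire", "dam")) {
    dangling <- unique(setdiff(r[[col]][!is.na(r[[col]])], r$id))
    if (length(dangling))
      add("parent_resolves", dangling, sprintf("%s id not on file", col))
  }

  # cycles, on raw parent links (ignoring the wild-founder truncation)
  pi <- parent_indices(p, wild_as_founder = FALSE)
  ok_parents <- (is.na(r$sire) | r$sire %in% r$id) &
    (is.na(r$dam) | r$dam %in% r$id)
  depth <- topo_depth(pi$sire, pi$dam, nrow(r))
  cyc <- which(is.na(depth) & ok_parents)
  if (length(cyc)) {
    on_cycle <- cyc[vapply(cyc, function(i)
      self_reachable(i, pi$sire, pi$dam), logical(1))]
    if (!length(on_cycle)) on_cycle <- cyc
    add("acyclic", r$id[on_cycle], "individual is its own ancestor")
  }

  for (col in c("sire", "dam")) {
    pidx <- idx[match(r[[col]], names(idx))]
    bad <- which(!is.na(pidx) & r$birth_date[pidx] >= r$birth_date)
    if (length(bad))
      add("chronology", r$id[bad],
          sprintf("%s born on/after offspring birth date", col))
  }

  bad <- which(!is.na(r$death_date) & r$death_date < r$birth_date)
  if (length(bad)) add("death_after_birth", r$id[bad],
                       "death date precedes birth date")

  if (length(v)) do.call(rbind, v)
  else data.frame(rule = character(), ids = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

# Is individual i an ancestor of itself? (bounded DFS over parent links)
self_reachable <- function(i, sire, dam, limit = 10000L) {
  stack <- c(sire[i], dam[i])
  seen <- integer(0)
  steps <- 0L
  while (length(stack)) {
    steps <- steps + 1L
    if (steps > limit) return(TRUE)
    cur <- stack[[1L]]
    stack <- stack[-1L]
    if (is.na(cur)) next
    if (cur == i) return(TRUE)
    if (cur %in% seen) next
    seen <- c(seen, cur)
    stack <- c(stack, sire[cur], dam[cur])
  }
  FALSE
}
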