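## Curated association-table model: loading/normalization, host-breadth
## profiles, polyphagy partitions, genus-level interaction matrices, the
## filters feeding the DEC* reconstruction, and main-host-family selection.

.assoc_required_cols <- c("fly_species", "host_species", "host_genus",
                          "host_family")
.assoc_statuses <- c("valid", "excluded_doubtful", "excluded_unidentified")

.normalize_label <- function(x) gsub("\\s+", " ", trimws(x))

#' Construct a validated association table
#'
#' Records are fly-by-host-species associations annotated with host genus and
#' family. Labels are lexically normalized (trimmed, internal whitespace
#' collapsed). Records flagged as excluded are retained but inert: every
#' downstream computation uses valid records only. Exact duplicate
#' (fly, host species) pairs among valid records are collapsed with a message.
#'
#' @param records data.frame with columns `fly_species`, `host_species`,
#'   `host_genus`, `host_family` and optionally `status` (one of
#'   `valid`, `excluded_doubtful`, `excluded_unidentified`; default `valid`).
#' @return an object of class `association_table` (a data.frame).
#' @export
association_table <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.assoc_required_cols, names(records))
  if (length(missing_cols))
    stop("association table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  rec <- records
  if (!"status" %in% names(rec)) rec$status <- "valid"
  rec$status[is.na(rec$status) | rec$status == ""] <- "valid"
  bad_status <- setdiff(unique(rec$status), .assoc_statuses)
  if (length(bad_status))
    stop("unknown status value(s): ", paste(bad_status, collapse = ", "))
  for (col in .assoc_required_cols)
    rec[[col]] <- .normalize_label(as.character(rec[[col]]))

  empty <- which(rec$status == "valid" &
                 (!nzchar(rec$fly_species) | !nzchar(rec$host_species) |
                  !nzchar(rec$host_genus) | !nzchar(rec$host_family)))
  if (length(empty))
    stop("valid record(s) with empty required field at row(s): ",
         paste(head(empty, 10), collapse = ", "))

  valid <- rec[rec$status == "valid", , drop = FALSE]
  # taxonomic consistency: species -> one genus, genus -> one family
  sp_gen <- unique(valid[, c("host_species", "host_genus")])
  dup_sp <- sp_gen$host_species[duplicated(sp_gen$host_species)]
  if (length(dup_sp))
    stop("host species mapped to more than one genus: ",
         paste(unique(dup_sp), collapse = ", "))
  gen_fam <- unique(valid[, c("host_genus", "host_family")])
  dup_gen <- gen_fam$host_genus[duplicated(gen_fam$host_genus)]
  if (length(dup_gen))
    stop("host genus mapped to more than one family: ",
         paste(unique(dup_gen), collapse = ", "))

  key <- paste(rec$fly_species, rec$host_species, sep = "\r")
  dup <- duplicated(key) & rec$status == "valid"
  if (any(dup)) {
    .msg(sum(dup), " duplicate (fly, host species) record(s) collapsed")
    rec <- rec[!dup, , drop = FALSE]
  }
  rownames(rec) <- NULL
  class(rec) <- c("association_table", "data.frame")
  rec
}

#' Load an association table from CSV/TSV
#'
#' The delimiter is taken from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma). See [association_table()] for the validation applied.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter; `NULL` (default) chooses from the extension.
#' @return an `association_table`.
#' @export
load_association_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
  association_table(raw)
}

#' Write an association table to TSV
#' @param table an `association_table`.
#' @param path output path.
#' @export
write_association_table <- function(table, path) {
  stopifnot(inherits(table, "association_table"))
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

.valid_records <- function(table) {
  stopifnot(inherits(table, "association_table"))
  table[table$status == "valid", , drop = FALSE]
}

#' Host-breadth profile per fly
#'
#' Counts distinct host species, genera and families per fly over valid
#' records. Host breadth in the signal analyses is the family count.
#'
#' @param table an `association_table`.
#' @return data.frame of class `breadth_profile` with columns `fly_species`,
#'   `n_host_species`, `n_host_genera`, `n_host_families`.
#' @export
host_breadth <- function(table) {
  v <- .valid_records(table)
  if (!nrow(v)) stop("no valid records")
  flies <- sort(unique(v$fly_species))
  prof <- data.frame(
    fly_species = flies,
    n_host_species = vapply(flies, function(f)
      length(unique(v$host_species[v$fly_species == f])), integer(1)),
    n_host_genera = vapply(flies, function(f)
      length(unique(v$host_genus[v$fly_species == f])), integer(1)),
    n_host_families = vapply(flies, function(f)
      length(unique(v$host_family[v$fly_species == f])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(prof) <- c("breadth_profile", "data.frame")
  prof
}

#' Binarize host breadth into a polyphagy state
#'
#' A fly is scored polyphagous (1) when it feeds on strictly more than
#' `threshold` host families; thresholds 2, 3 and 4 define the partitions
#' used in the signal analysis.
#'
#' @param profile a `breadth_profile`.
#' @param threshold integer >= 1.
#' @return list with `trait` (named 0/1 integer vector over flies),
#'   `n_polyphagous`, and `threshold`.
#' @export
binarize_polyphagy <- function(profile, threshold) {
  stopifnot(inherits(profile, "breadth_profile"),
            is.numeric(threshold), threshold >= 1)
  trait <- as.integer(profile$n_host_families > threshold)
  names(trait) <- profile$fly_species
  list(trait = trait, n_polyphagous = sum(trait), threshold = threshold)
}

#' Genus-level binary interaction matrix
#'
#' Rows are flies, columns every host genus with at least one valid
#' association in the table; an entry is 1 iff the fly has a valid
#' association with any species of that genus.
#'
#' @param table an `association_table`.
#' @return a binary integer matrix with fly rownames and genus colnames.
#' @export
interaction_matrix <- function(table) {
  v <- .valid_records(table)
  if (!nrow(v)) stop("no valid records")
  flies <- sort(unique(v$fly_species))
  genera <- sort(unique(v$host_genus))
  m <- matrix(0L, length(flies), length(genera),
              dimnames = list(flies, genera))
  m[cbind(match(v$fly_species, flies), match(v$host_genus, genera))] <- 1L
  m
}

#' Filter flies for ancestral host-range reconstruction
#'
#' Drops extreme polyphages (feeding on `max_families` or more host
#' families), whose current diet likely overruns the ancestral host range,
#' plus any explicitly named exclusions.
#'
#' @param table an `association_table`.
#' @param max_families flies with `n_host_families >= max_families` are
#'   removed (default 20).
#' @param exclude character vector of fly names to drop regardless of breadth.
#' @return list with `table` (filtered `association_table`) and `retained`
#'   (character vector of fly names kept).
#' @export
filter_for_dec <- function(table, max_families = 20, exclude = character()) {
  prof <- host_breadth(table)
  missing_excl <- setdiff(exclude, prof$fly_species)
  if (length(missing_excl))
    warning("excluded fly not present in table: ",
            paste(missing_excl, collapse = ", "))
  drop <- prof$fly_species[prof$n_host_families >= max_families]
  retained <- setdiff(prof$fly_species, union(drop, exclude))
  if (!length(retained))
    warning("no flies retained after filtering; result is empty")
  out <- table[table$fly_species %in% retained |
               table$status != "valid", , drop = FALSE]
  class(out) <- class(table)
  list(table = out, retained = retained)
}

#' Most commonly used host families
#'
#' Ranks families either by the number of distinct host species they
#' contribute (`n_host_species`, default) or by the number of fly species
#' feeding on them (`n_fly_species`). Ties are broken alphabetically and
#' reported with a message when they straddle rank k.
#'
#' @param table an `association_table`.
#' @param k number of families to return (default 9).
#' @param rank_by ranking criterion.
#' @return character vector of k family names, most used first.
#' @export
main_host_families <- function(table, k = 9,
                               rank_by = c("n_host_species", "n_fly_species")) {
  rank_by <- match.arg(rank_by)
  v <- .valid_records(table)
  fams <- sort(unique(v$host_family))
  if (k > length(fams))
    stop("k = ", k, " exceeds the ", length(fams), " families present")
  n <- if (rank_by == "n_host_species") {
    vapply(fams, function(f)
      length(unique(v$host_species[v$host_family == f])), integer(1))
  } else {
    vapply(fams, function(f)
      length(unique(v$fly_species[v$host_family == f])), integer(1))
  }
  ord <- order(-n, fams)
  ranked <- fams[ord]
  counts <- n[ord]
  if (k < length(fams) && counts[k] == counts[k + 1])
    .msg("tie at rank ", k, " (count ", counts[k],
         "); alphabetical order decides")
  ranked[seq_len(k)]
}

#' Tip range states over a set of host families
#'
#' For each fly the subset of `families` it has at least one valid
#' association with. The DEC* state space forbids the null range, so a fly
#' using none of the listed families is an error (filter it out first).
#'
#' @param table an `association_table`.
#' @param families character vector of family names defining the range units.
#' @return named list mapping fly name to a character vector of families.
#' @export
tip_range_states <- function(table, families) {
  v <- .valid_records(table)
  flies <- sort(unique(v$fly_species))
  states <- lapply(flies, function(f)
    intersect(families, unique(v$host_family[v$fly_species == f])))
  names(states) <- flies
  empty <- flies[lengths(states) == 0L]
  if (length(empty))
    stop("fly species with no association in the listed families ",
         "(null ranges are disallowed): ", paste(empty, collapse = ", "))
  states
}
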