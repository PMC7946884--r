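#' Construct a validated multi-state chemical-shift table
#'
#' A shift table holds backbone amide chemical shifts (delta 1H, delta 15N, in
#' ppm) for a set of residues observed in an ordered series of ligation states,
#' optionally with per-peak linewidths. It is the common substrate of CSP,
#' CHESCA and CONCISE analyses.
#'
#' @param records data frame with columns `residue_id`, `state`, `delta_H`,
#'   `delta_N`, and optionally `residue_label`, `lw_H`, `lw_N`.
#' @param states character vector giving the canonical state order. Defaults to
#'   the order of first appearance in `records`. By convention the apo form is
#'   first and the ternary (nucleotide + pseudo-substrate) form last.
#' @param protein_id identifier carried through outputs.
#' @return A data frame of class `"shift_table"` with attributes `states` and
#'   `protein_id`.
#' @examples
#' df <- data.frame(residue_id = c(55L, 55L), state = c("apo", "ADP"),
#'                  delta_H = c(8.31, 8.35), delta_N = c(119.4, 119.9))
#' st <- shift_table(df, states = c("apo", "ADP"))
#' shift_states(st)
#' @export
shift_table <- function(records, states = NULL, protein_id = "protein") {
  stopifnot(is.data.frame(records))
  required <- c("residue_id", "state", "delta_H", "delta_N")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("shift table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records$residue_id <- as.integer(records$residue_id)
  records$state <- as.character(records$state)
  if (is.null(records$residue_label))
    records$residue_label <- paste0("X", records$residue_id)
  if (is.null(records$lw_H)) records$lw_H <- NA_real_
  if (is.null(records$lw_N)) records$lw_N <- NA_real_
  records <- records[, c("residue_id", "residue_label", "state",
                         "delta_H", "delta_N", "lw_H", "lw_N")]

  bad <- !is.finite(records$delta_H) | !is.finite(records$delta_N)
  if (any(bad))
    stop("non-finite chemical shifts for residue(s) ",
         paste(unique(records$residue_id[bad]), collapse = ", "), call. = FALSE)
  lw_bad <- (!is.na(records$lw_H) & records$lw_H <= 0) |
            (!is.na(records$lw_N) & records$lw_N <= 0)
  if (any(lw_bad))
    stop("linewidths must be > 0 where present", call. = FALSE)

  key <- paste(records$residue_id, records$state, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (residue, state) pair(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)

  if (is.null(states)) states <- unique(records$state)
  unknown <- setdiff(records$state, states)
  if (length(unknown) > 0L)
    stop("record state(s) not in declared state order: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  structure(records,
            states = as.character(states),
            protein_id = protein_id,
            class = c("shift_table", "data.frame"))
}

#' @rdname shift_table
#' @param table a `shift_table`.
#' @export
shift_states <- function(table) attr(table, "states")

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("Shift table '%s': %d records, %d residues, states: %s\n",
              attr(x, "protein_id"), nrow(x), length(unique(x$residue_id)),
              paste(attr(x, "states"), collapse = " -> ")))
  invisible(x)
}

#' Read a chemical-shift table from disk
#'
#' Reads per-residue amide shifts from a delimited table
#' (`residue_id,residue_label,state,delta_H,delta_N[,lw_H,lw_N]`) or from a
#' Sparky-style peak list, where each line carries an assignment string of the
#' form `<Res><Num>N-H` followed by the 15N and 1H shift (one ligation state
#' per file, supplied via `state`). Rows whose shifts cannot be parsed are
#' dropped with a message giving the count.
#'
#' @param path file to read.
#' @param format one of `"csv"`, `"tsv"`, `"sparky"`.
#' @param state state label for a Sparky list (required for `format =
#'   "sparky"`).
#' @param states optional canonical state order passed to [shift_table()].
#' @param protein_id identifier carried through outputs.
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path, format = c("csv", "tsv", "sparky"),
                             state = NULL, states = NULL,
                             protein_id = "protein") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "sparky") {
    if (is.null(state))
      stop("a 'state' label is required when reading a Sparky list",
           call. = FALSE)
    return(read_sparky_list(path, state = state, states = states,
                            protein_id = protein_id))
  }

  sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("residue_id", "state", "delta_H", "delta_N")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("delta_H", "delta_N", "lw_H", "lw_N"))
    if (!is.null(raw[[col]])) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  parseable <- is.finite(raw$delta_H) & is.finite(raw$delta_N) &
               !is.na(suppressWarnings(as.integer(raw$residue_id)))
  n_drop <- sum(!parseable)
  if (n_drop > 0L)
    message(n_drop, " row(s) with unparseable shifts dropped from ", path)
  shift_table(raw[parseable, , drop = FALSE], states = states,
              protein_id = protein_id)
}

# Sparky assignment dialect: "<one-letter residue><number>N-H  wN  wH".
read_sparky_list <- function(path, state, states = NULL,
                             protein_id = "protein") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^(Assignment|#)", lines)]
  pat <- "^([A-Za-z]{1,3})([0-9]+)N-H$"
  ids <- integer(0); labels <- character(0); dN <- numeric(0); dH <- numeric(0)
  n_skipped <- 0L
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 3L || !grepl(pat, tok[1])) { n_skipped <- n_skipped + 1L; next }
    wN <- suppressWarnings(as.numeric(tok[2]))
    wH <- suppressWarnings(as.numeric(tok[3]))
    if (!is.finite(wN) || !is.finite(wH)) { n_skipped <- n_skipped + 1L; next }
    ids <- c(ids, as.integer(sub(pat, "\\2", tok[1])))
    labels <- c(labels, paste0(sub(pat, "\\1", tok[1]), sub(pat, "\\2", tok[1])))
    dN <- c(dN, wN); dH <- c(dH, wH)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " unparsable assignment line(s) skipped in ", path,
            call. = FALSE)
  shift_table(data.frame(residue_id = ids, residue_label = labels,
                         state = state, delta_H = dH, delta_N = dN,
                         stringsAsFactors = FALSE),
              states = states, protein_id = protein_id)
}

#' Write a shift table to CSV
#'
#' Inverse of [read_shift_table()]; shifts are written at full precision so a
#' write/read round trip reproduces every record exactly.
#'
#' @param table a [shift_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  df <- as.data.frame(table)
  for (col in c("delta_H", "delta_N", "lw_H", "lw_N"))
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Residues observed in every requested state
#'
#' CHESCA and CONCISE require each residue to be observed in all analyzed
#' states; residues with incomplete state coverage are excluded upstream.
#'
#' @param table a [shift_table()].
#' @param states states that must all be covered; defaults to every state of
#'   the table.
#' @return Sorted integer vector of residue ids complete across `states`.
#' @export
complete_residues <- function(table, states = NULL) {
  stopifnot(inherits(table, "shift_table"))
  if (is.null(states)) states <- shift_states(table)
  unknown <- setdiff(states, shift_states(table))
  if (length(unknown) > 0L)
    stop("unknown state label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sub <- table[table$state %in% states, , drop = FALSE]
  counts <- table(sub$residue_id[!duplicated(paste(sub$residue_id, sub$state))])
  sort(as.integer(names(counts)[counts == length(states)]))
}

#' Construct or read a residue-to-community map
#'
#' Communities are predefined functional groups of residues (e.g. the nine
#' structural/functional communities of the kinase core, ComA--ComH plus
#' ComF1). Each residue belongs to at most one community.
#'
#' @param assignments data frame with columns `residue_id` and `community`.
#' @param community_names optional named character vector mapping community
#'   labels to functional descriptions.
#' @return Data frame of class `"community_map"`.
#' @export
community_map <- function(assignments, community_names = NULL) {
  stopifnot(is.data.frame(assignments))
  missing_cols <- setdiff(c("residue_id", "community"), names(assignments))
  if (length(missing_cols) > 0L)
    stop("community map is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  assignments$residue_id <- as.integer(assignments$residue_id)
  assignments$community <- as.character(assignments$community)
  dup <- duplicated(assignments$residue_id)
  if (any(dup))
    stop("residue(s) assigned to more than one community: ",
         paste(unique(assignments$residue_id[dup]), collapse = ", "),
         call. = FALSE)
  if (nrow(assignments) == 0L)
    warning("community map is empty", call. = FALSE)
  structure(assignments[, c("residue_id", "community")],
            community_names = community_names,
            class = c("community_map", "data.frame"))
}

#' @rdname community_map
#' @param path two-column CSV (`residue_id,community`).
#' @export
read_community_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) data.frame(residue_id = integer(0),
                                   community = character(0)))
  community_map(raw)
}

#' @rdname community_map
#' @param map a `community_map`.
#' @export
community_sizes <- function(map) {
  stopifnot(inherits(map, "community_map"))
  tab <- table(map$community)
  stats::setNames(as.integer(tab), names(tab))
}
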