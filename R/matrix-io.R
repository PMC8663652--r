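#' Construct a discrete character matrix
#'
#' A `char_matrix` holds a rectangular taxa-by-characters table of small
#' integer states (0-9) with `NA` marking unknown ("?") entries.  Characters
#' are conventionally numbered from 0, matching the usual presentation of
#' morphological character lists.
#'
#' @param states integer matrix (taxa in rows, characters in columns);
#'   entries in 0..9 or `NA` for missing.
#' @param taxa character vector of unique, non-empty taxon labels; defaults
#'   to `rownames(states)`.
#' @return an object of class `char_matrix` with elements `states`, `taxa`,
#'   `n_taxa` and `n_chars`.
#' @export
char_matrix <- function(states, taxa = rownames(states)) {
  if (!is.matrix(states)) states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(taxa)) stop("taxon labels are required")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(states))
    stop("length of 'taxa' must equal nrow(states)")
  if (anyDuplicated(taxa))
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1])
  if (any(!nzchar(taxa))) stop("taxon names must be non-empty")
  ok <- is.na(states) | (states >= 0L & states <= 9L)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("state out of range 0-9 at taxon '", taxa[bad[1]],
         "', character ", bad[2] - 1L)
  }
  all_missing <- colSums(!is.na(states)) == 0L
  if (any(all_missing))
    stop("character ", which(all_missing)[1] - 1L,
         " has no observed states (all missing)")
  rownames(states) <- taxa
  colnames(states) <- NULL
  structure(list(states = states, taxa = taxa,
                 n_taxa = nrow(states), n_chars = ncol(states)),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Discrete character matrix: ", x$n_taxa, " taxa x ", x$n_chars,
      " characters\n", sep = "")
  cat("  missing entries: ", sum(is.na(x$states)), "\n", sep = "")
  cat("  taxa: ", paste(x$taxa, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`==.char_matrix` <- function(e1, e2) {
  identical(e1$taxa, e2$taxa) &&
    identical(dim(e1$states), dim(e2$states)) &&
    isTRUE(all.equal(e1$states, e2$states))
}

#' Per-character optimization settings
#'
#' Describes, for each character of a matrix, the optimization mode
#' (`"unordered"` Fitch, `"ordered"` Wagner/additive, or `"irreversible"`
#' increase-only), an integer weight (>= 1) and an activity flag.
#'
#' @param n_chars number of characters.
#' @param mode character vector (recycled) of modes.
#' @param weight integer vector (recycled) of positive weights.
#' @param active logical vector (recycled).
#' @return object of class `char_type_spec`.
#' @export
char_type_spec <- function(n_chars, mode = "unordered", weight = 1L,
                           active = TRUE) {
  mode <- match.arg(rep_len(mode, n_chars),
                    c("unordered", "ordered", "irreversible"),
                    several.ok = TRUE)
  mode <- rep_len(mode, n_chars)
  weight <- rep_len(as.integer(weight), n_chars)
  active <- rep_len(as.logical(active), n_chars)
  if (any(weight < 1L)) stop("all weights must be >= 1")
  structure(list(mode = mode, weight = weight, active = active,
                 n_chars = n_chars),
            class = "char_type_spec")
}

#' @export
print.char_type_spec <- function(x, ...) {
  cat("Character type spec for", x$n_chars, "characters\n")
  cat("  modes: ", paste(names(table(x$mode)), table(x$mode),
                         sep = ":", collapse = ", "), "\n", sep = "")
  cat("  weights: ", paste(unique(x$weight), collapse = ", "),
      "; active: ", sum(x$active), "\n", sep = "")
  invisible(x)
}

## internal: check that a spec fits a matrix (and make a default one)
spec_for <- function(m, spec = NULL) {
  if (is.null(spec)) return(char_type_spec(m$n_chars))
  stopifnot(inherits(spec, "char_type_spec"))
  if (spec$n_chars != m$n_chars)
    stop("type spec covers ", spec$n_chars, " characters but matrix has ",
         m$n_chars)
  spec
}

#' Parse a character matrix from text
#'
#' Three dialects are supported.  `"plain"` is one taxon per line: a label
#' followed by its digit string; whitespace inside the digit string is
#' ignored, so a ruled table can be pasted as is.  `"nexus"` expects a
#' DATA or CHARACTERS block with DIMENSIONS and MATRIX statements.
#' `"tnt"` expects a Hennig86-style `xread` block (`nchar ntax` header).
#' The only missing symbol is `"?"`; polymorphic entries such as `{01}`
#' are rejected with an error rather than silently coerced.
#'
#' @param text a single string or a character vector of lines.
#' @param dialect one of `"plain"`, `"nexus"`, `"tnt"`.
#' @return a validated [char_matrix()].
#' @seealso [write_matrix()], [read_matrix()]
#' @export
parse_matrix <- function(text, dialect = c("plain", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  switch(dialect,
         plain = parse_plain(lines),
         nexus = parse_nexus(lines),
         tnt = parse_tnt(lines))
}

#' Read a character matrix from a file
#'
#' @param file path to a text file.
#' @inheritParams parse_matrix
#' @return a validated [char_matrix()].
#' @export
read_matrix <- function(file, dialect = c("plain", "nexus", "tnt")) {
  parse_matrix(readLines(file, warn = FALSE), dialect)
}

## digits-and-? string -> integer vector with NA; 'where' names the taxon
decode_states <- function(s, where) {
  ch <- strsplit(s, "")[[1]]
  bad <- !(ch %in% c(as.character(0:9), "?"))
  if (any(bad)) {
    if (any(ch %in% c("{", "(", "[")))
      stop("polymorphic state entries are not supported (taxon '", where,
           "')")
    stop("undeclared state symbol '", ch[bad][1], "' at position ",
         which(bad)[1], " of taxon '", where, "'")
  }
  match(ch, as.character(0:9)) - 1L   # "?" -> NA
}

rows_to_matrix <- function(names, strings, n_chars = NULL) {
  poly <- grepl("[{(\\[]", strings)
  if (any(poly))
    stop("polymorphic state entries are not supported (taxon '",
         names[poly][1], "')")
  lens <- nchar(strings)
  want <- if (is.null(n_chars)) lens[1] else n_chars
  if (any(lens != want))
    stop("ragged rows: taxon '", names[which(lens != want)[1]],
         "' has ", lens[which(lens != want)[1]], " states, expected ", want)
  states <- do.call(rbind, Map(decode_states, strings, names))
  char_matrix(states, taxa = names)
}

parse_plain <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no data rows found")
  toks <- strsplit(lines, "[ \t]+")
  names <- vapply(toks, `[`, "", 1L)
  strings <- vapply(toks, function(t) paste(t[-1], collapse = ""), "")
  if (any(!nzchar(strings))) stop("taxon '", names[!nzchar(strings)][1],
                                  "' has no character states")
  rows_to_matrix(names, strings)
}

parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")
  dim_m <- regmatches(txt, regexpr(
    "DIMENSIONS[^;]*;", txt, ignore.case = TRUE))
  if (!length(dim_m)) stop("NEXUS DIMENSIONS statement not found")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                         ignore.case = TRUE))
  nchr <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                         ignore.case = TRUE))
  mat_at <- regexpr("MATRIX\\s", txt, ignore.case = TRUE)
  if (mat_at < 0) stop("NEXUS MATRIX statement not found")
  body <- substr(txt, mat_at + 6, nchar(txt))
  body <- substr(body, 1, regexpr(";", body, fixed = TRUE) - 1)
  rows <- trimws(unlist(strsplit(body, "\n")))
  rows <- rows[nzchar(rows)]
  toks <- strsplit(rows, "[ \t]+")
  names <- gsub("^'|'$", "", vapply(toks, `[`, "", 1L))
  strings <- vapply(toks, function(t) paste(t[-1], collapse = ""), "")
  m <- rows_to_matrix(names, strings, n_chars = nchr)
  if (!is.na(ntax) && m$n_taxa != ntax)
    stop("NEXUS declares NTAX=", ntax, " but ", m$n_taxa, " rows found")
  m
}

parse_tnt <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  x_at <- regexpr("xread", txt, ignore.case = TRUE)
  if (x_at < 0) stop("TNT 'xread' block not found")
  body <- substr(txt, x_at + 5, nchar(txt))
  # optional quoted title
  body <- sub("^\\s*'[^']*'", "", body)
  hdr <- regmatches(body, regexpr("^\\s*([0-9]+)\\s+([0-9]+)", body))
  if (!length(hdr)) stop("TNT header 'nchar ntax' not found")
  nums <- as.integer(strsplit(trimws(hdr), "\\s+")[[1]])
  nchr <- nums[1]; ntax <- nums[2]
  body <- sub("^\\s*[0-9]+\\s+[0-9]+", "", body)
  body <- substr(body, 1, regexpr(";", body, fixed = TRUE) - 1)
  rows <- trimws(unlist(strsplit(body, "\n")))
  rows <- rows[nzchar(rows)]
  toks <- strsplit(rows, "[ \t]+")
  names <- vapply(toks, `[`, "", 1L)
  strings <- vapply(toks, function(t) paste(t[-1], collapse = ""), "")
  m <- rows_to_matrix(names, strings, n_chars = nchr)
  if (m$n_taxa != ntax)
    stop("TNT declares ", ntax, " taxa but ", m$n_taxa, " rows found")
  m
}

#' Serialize a character matrix
#'
#' The emitted text re-parses to an equal matrix in the same dialect
#' (lossless round trip); missing entries are written as `"?"`.
#'
#' @param m a [char_matrix()].
#' @inheritParams parse_matrix
#' @return a character vector of lines.
#' @export
write_matrix <- function(m, dialect = c("plain", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "char_matrix"))
  enc <- apply(m$states, 1, function(r)
    paste(ifelse(is.na(r), "?", as.character(r)), collapse = ""))
  lab <- gsub("[ \t]", "_", m$taxa)
  pad <- formatC(lab, width = max(nchar(lab)) + 2, flag = "-")
  rows <- paste0(pad, enc)
  switch(dialect,
         plain = rows,
         nexus = c("#NEXUS", "BEGIN DATA;",
                   paste0("  DIMENSIONS NTAX=", m$n_taxa,
                          " NCHAR=", m$n_chars, ";"),
                   "  FORMAT SYMBOLS=\"0123456789\" MISSING=?;",
                   "  MATRIX", paste0("    ", rows), "  ;", "END;"),
         tnt = c("xread", paste(m$n_chars, m$n_taxa), rows, ";"))
}

#' Write a character matrix to a file
#'
#' @inheritParams write_matrix
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_matrix_file <- function(m, file, dialect = c("plain", "nexus", "tnt")) {
  writeLines(write_matrix(m, dialect), file)
  invisible(file)
}

#' The bundled Bicorniphontodes study matrix
#'
#' Returns the seven-taxon, 41-character morphological matrix for six
#' *Bicorniphontodes* species plus the outgroup *Laophontodes typicus*,
#' together with its character type specification and the outgroup label.
#' Characters are numbered 0-40.  States are 0 (presumed plesiomorphic),
#' 1-2 (presumed apomorphic) and `NA` for the two unknown entries
#' (characters 25-26 of *B. bicornis*).  The four three-state characters
#' (6, 7, 39 and 40) describe progressive series (process development,
#' protuberance and tube-pore counts) and are treated as ordered; all
#' binary characters are unordered.  All weights are 1 and all characters
#' active.
#'
#' @return a list with elements `matrix` ([char_matrix()]),
#'   `spec` ([char_type_spec()]) and `outgroup` (taxon label).
#' @export
bundled_study_matrix <- function() {
  f <- system.file("extdata", "bicorniphontodes_table1.txt",
                   package = "morphpars")
  m <- read_matrix(f, dialect = "plain")
  spec <- char_type_spec(m$n_chars)
  spec$mode[c(6, 7, 39, 40) + 1L] <- "ordered"
  list(matrix = m, spec = spec, outgroup = "Laophontodes_typicus")
}
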