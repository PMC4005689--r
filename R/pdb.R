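## Minimal PDB ATOM/HETATM reader and writer.  No pre-installed R package
## parses PDB coordinate files, so the fixed-column format is read directly;
## only the fields the structure metrics need are kept.

#' Read ATOM/HETATM records from a PDB file
#'
#' Alternate locations are resolved to the highest-occupancy conformer per
#' (chain, residue, atom name).  Atom names are normalised to the prime
#' convention (`*` -> `'`).
#'
#' @param path PDB file.
#' @return data.frame with columns `record`, `serial`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `occupancy`, `element`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  fx <- function(from, to) trimws(substr(lines, from, to))
  df <- data.frame(
    record = fx(1, 6),
    serial = as.integer(fx(7, 11)),
    name = chartr("*", "'", fx(13, 16)),
    altloc = fx(17, 17),
    resname = fx(18, 20),
    chain = fx(22, 22),
    resno = as.integer(fx(23, 26)),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    occupancy = suppressWarnings(as.numeric(fx(55, 60))),
    element = toupper(fx(77, 78)),
    stringsAsFactors = FALSE)
  df$occupancy[is.na(df$occupancy)] <- 1
  blank <- df$element == ""
  df$element[blank] <- guess_element(df$name[blank])
  ## altloc resolution: highest occupancy wins, first on ties
  key <- paste(df$chain, df$resno, df$name, sep = "\r")
  df <- df[order(key, -df$occupancy), , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resno, df$name, sep = "\r")), ,
           drop = FALSE]
  df <- df[order(df$serial), setdiff(names(df), "altloc"), drop = FALSE]
  rownames(df) <- NULL
  df
}

guess_element <- function(name) {
  ## PDB atom names for nucleic acids start with the element letter once
  ## leading digits are stripped (e.g. "C1'", "O4'", "1H2")
  toupper(substr(sub("^[0-9']*", "", name), 1, 1))
}

#' Write atoms as a PDB file
#'
#' Emits well-formed fixed-column ATOM records (used by the synthetic
#' structure generator and for round-trip testing of [read_pdb()]).
#'
#' @param atoms data.frame as returned by [read_pdb()] (minimally `name`,
#'   `resname`, `chain`, `resno`, `x`, `y`, `z`; `element` optional).
#' @param path output path.
#' @export
write_pdb <- function(atoms, path) {
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  name4 <- ifelse(nchar(atoms$name) < 4L, paste0(" ", atoms$name), atoms$name)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name4, atoms$resname, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
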