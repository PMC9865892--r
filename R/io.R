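#' Read a single-frame coordinate file
#'
#' Supported dialects: GRO-format (fixed-width, nm) and PDB-format
#' (ATOM/HETATM records, Angstrom, CRYST1 box). Coordinates are converted
#' to nm regardless of source units. A missing or unreadable box is an
#' error; triclinic boxes are rejected as unsupported.
#'
#' @param path file to read
#' @param format "gro", "pdb" or "auto" (by file extension)
#' @return list with elements \code{atoms} (an [atom_table()]) and
#'   \code{frame} (an [md_frame()])
#' @export
load_structure <- function(path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  switch(format, gro = read_gro(path), pdb = read_pdb(path))
}

# element inferred from atom name: leading letters, Na/Cl special-cased
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(atom_name)))
  el <- substr(nm, 1, 1)
  el[nm %in% c("NA", "SOD")] <- "Na"
  el[nm %in% c("CL", "CLA")] <- "Cl"
  el
}

#' @rdname load_structure
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("malformed GRO file (too short): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file: atom count on line 2 unreadable")
  if (length(lines) < n + 3) stop("malformed GRO file: missing box line")
  rec <- lines[3:(n + 2)]
  resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resnm <- trimws(substr(rec, 6, 10))
  atnm <- trimws(substr(rec, 11, 15))
  atid <- suppressWarnings(as.integer(substr(rec, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record at line ", bad[1] + 2, ": ", rec[bad[1]])
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop("malformed GRO file: box line unreadable")
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
    stop("triclinic boxes are not supported")
  atoms <- atom_table(atom_name = atnm, element = infer_element(atnm),
                      residue_name = resnm, residue_id = resid,
                      atom_id = if (anyNA(atid)) NULL else atid,
                      validate = FALSE)
  validate_atom_table(atoms)
  list(atoms = atoms, frame = md_frame(cbind(x, y, z), boxv[1:3]))
}

#' @rdname load_structure
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cry)) stop("PDB file has no CRYST1 record (missing box)")
  abc <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15),
                                       substr(cry[1], 16, 24),
                                       substr(cry[1], 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(cry[1], 34, 40),
                                       substr(cry[1], 41, 47),
                                       substr(cry[1], 48, 54))))
  if (anyNA(abc)) stop("malformed CRYST1 record")
  if (!anyNA(ang) && any(abs(ang - 90) > 1e-6))
    stop("triclinic boxes are not supported")
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("PDB file has no ATOM/HETATM records")
  rl <- lines[rec]
  atnm <- trimws(substr(rl, 13, 16))
  resnm <- trimws(substr(rl, 18, 21))
  resid <- suppressWarnings(as.integer(substr(rl, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(rl, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rl, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rl, 47, 54)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed PDB record at line ", rec[bad[1]], ": ", rl[bad[1]])
  el <- trimws(substr(rl, 77, 78))
  el <- ifelse(nchar(el) > 0,
               paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2))),
               infer_element(atnm))
  atoms <- atom_table(atom_name = atnm, element = el,
                      residue_name = resnm, residue_id = resid,
                      validate = FALSE)
  validate_atom_table(atoms)
  # PDB is in Angstrom
  list(atoms = atoms, frame = md_frame(cbind(x, y, z) / 10, abc / 10))
}

#' Write a single frame in GRO format
#'
#' @param atoms an [atom_table()]
#' @param frame an [md_frame()]
#' @param path output file
#' @param title header line
#' @export
write_gro <- function(atoms, frame, path, title = "written by lamellipid") {
  n <- nrow(atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, sprintf("%5d", n)), con)
  # GRO residue/atom numbers are mod 1e5
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   atoms$residue_id %% 100000L, atoms$residue_name,
                   substr(atoms$atom_name, 1, 5), atoms$atom_id %% 100000L,
                   frame$coords[, 1], frame$coords[, 2], frame$coords[, 3])
  writeLines(lines, con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]), con)
  invisible(path)
}

#' Write a single frame in PDB format (coordinates converted to Angstrom)
#' @inheritParams write_gro
#' @export
write_pdb <- function(atoms, frame, path, title = "written by lamellipid") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", title), con)
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
                     90, 90, 90), con)
  lines <- sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   atoms$atom_id %% 100000L, substr(atoms$atom_name, 1, 4),
                   substr(atoms$residue_name, 1, 4), atoms$residue_id %% 10000L,
                   frame$coords[, 1] * 10, frame$coords[, 2] * 10,
                   frame$coords[, 3] * 10, atoms$element)
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in the plain-text LAMTRJ container
#'
#' Format (all whitespace-delimited, coordinates in nm, times in ps):
#' \preformatted{
#' LAMTRJ 1
#' NATOMS <n>
#' ATOMS
#' <atom_id> <atom_name> <element> <residue_name> <residue_id> <mass>  (n lines)
#' FRAME <time> <Lx> <Ly> <Lz>
#' <x> <y> <z>                                                         (n lines)
#' ... further FRAME blocks ...
#' END
#' }
#'
#' @param traj an [md_trajectory()]
#' @param path output file
#' @param digits coordinate precision (decimal places)
#' @export
write_trajectory <- function(traj, path, digits = 5) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  writeLines(c("LAMTRJ 1", paste("NATOMS", nrow(at)), "ATOMS"), con)
  writeLines(sprintf("%d %s %s %s %d %.6f", at$atom_id, at$atom_name,
                     at$element, at$residue_name, at$residue_id, at$mass), con)
  fmt <- sprintf("%%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in traj$frames) {
    writeLines(sprintf("FRAME %.6f %.6f %.6f %.6f", f$time,
                       f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf(fmt, f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a LAMTRJ trajectory container
#'
#' @param path file written by [write_trajectory()]
#' @return an [md_trajectory()]
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "LAMTRJ"))
    stop("not a LAMTRJ file: ", path)
  n <- as.integer(strsplit(lines[2], "\\s+")[[1]][2])
  if (is.na(n)) stop("malformed NATOMS line")
  if (lines[3] != "ATOMS") stop("malformed LAMTRJ: expected ATOMS block")
  arec <- do.call(rbind, strsplit(lines[4:(3 + n)], "\\s+"))
  atoms <- atom_table(atom_name = arec[, 2], element = arec[, 3],
                      residue_name = arec[, 4],
                      residue_id = as.integer(arec[, 5]),
                      mass = as.numeric(arec[, 6]),
                      atom_id = as.integer(arec[, 1]))
  pos <- 4 + n
  frames <- list()
  while (pos <= length(lines) && startsWith(lines[pos], "FRAME")) {
    hdr <- as.numeric(strsplit(lines[pos], "\\s+")[[1]][-1])
    if (length(hdr) != 4 || anyNA(hdr))
      stop("malformed FRAME header at line ", pos)
    block <- lines[(pos + 1):(pos + n)]
    xyz <- matrix(as.numeric(unlist(strsplit(block, "\\s+"))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) stop("malformed coordinate block after line ", pos)
    frames[[length(frames) + 1L]] <- md_frame(xyz, hdr[2:4], hdr[1])
    pos <- pos + n + 1
  }
  if (!length(frames)) stop("LAMTRJ file contains no frames")
  md_trajectory(atoms, frames)
}

#' Write a tidy result table as CSV with a metadata header
#'
#' Metadata are written as leading \code{# key: value} comment lines so the
#' file remains a valid CSV for readers that skip comments.
#'
#' @param df data.frame of results
#' @param path output file
#' @param meta named list of metadata (units, selections, frame range...)
#' @export
write_result_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, function(v) paste(format(v), collapse = " "),
                            character(1))), con)
  close(con)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}
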