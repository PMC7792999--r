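# Reading/writing crystallographic coordinate files and ensemble frames.
# PDB (and mmCIF) parsing is delegated to bio3d; this layer adds frame
# handling, deuterium/altloc-preserving validation and the frame-table
# dialect used for plain-text ensembles.

.guess_element <- function(name) {
  # PDB atom-name convention: element is the first alphabetic character,
  # except deuterium/hydrogen names which may start with a digit (e.g. 1HB).
  nm <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(nm, 1L, 1L))
  two <- toupper(substr(nm, 1L, 2L))
  el[two %in% c("CL", "BR", "NA", "MG", "FE", "ZN", "MN", "SE")] <-
    two[two %in% c("CL", "BR", "NA", "MG", "FE", "ZN", "MN", "SE")]
  el
}

.atoms_from_bio3d <- function(at) {
  el <- toupper(trimws(at$elesy))
  el[is.na(el) | !nzchar(el)] <- .guess_element(at$elety[is.na(el) | !nzchar(el)])
  data.frame(serial = at$eleno,
             name = trimws(at$elety),
             altloc = ifelse(is.na(at$alt), "", at$alt),
             resname = trimws(at$resid),
             chain = ifelse(is.na(at$chain), "", at$chain),
             resno = at$resno,
             inscode = ifelse(is.na(at$insert), "", at$insert),
             element = el,
             occupancy = ifelse(is.na(at$o), 1, at$o),
             b = ifelse(is.na(at$b), 0, at$b),
             hetatm = at$type == "HETATM",
             stringsAsFactors = FALSE)
}

.check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop(sprintf("malformed coordinate record at line %d of %s (truncated)",
                                     i, path), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed coordinate record at line %d of %s (unparseable coordinates)",
                   i, path), call. = FALSE)
  }
  invisible(lines)
}

#' Read a crystallographic structure (PDB or mmCIF)
#'
#' All ATOM/HETATM sites are captured with element, altloc and occupancy;
#' deuterium is preserved as element `"D"` (never renamed); multi-MODEL files
#' yield one frame per model. Malformed records, unknown elements and
#' duplicate atom keys (chain, residue, insertion code, atom name, altloc)
#' are errors.
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"mmcif"`.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "pdb") {
    lines <- .check_pdb_records(path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                            verbose = FALSE))
    cell <- NULL; sg <- NULL
    cry <- grep("^CRYST1", lines, value = TRUE)
    if (length(cry)) {
      cell <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                                            substr(cry[1], 25, 33), substr(cry[1], 34, 40),
                                            substr(cry[1], 41, 47), substr(cry[1], 48, 54))))
      sg <- trimws(substr(cry[1], 56, 66))
    }
  } else {
    pdb <- suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    cell <- NULL; sg <- NULL
  }
  atoms <- .atoms_from_bio3d(pdb$atom)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nfr <- nrow(xyz)
  arr <- array(NA_real_, dim = c(nrow(atoms), 3L, nfr))
  for (f in seq_len(nfr)) arr[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  structure_model(atoms, arr, cell = cell, spacegroup = sg, source = path)
}

.fmt_pdb_line <- function(at, xyz) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(at$hetatm, "HETATM", "ATOM"),
          at$serial %% 100000L,
          ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name),
          ifelse(nzchar(at$altloc), at$altloc, " "),
          at$resname, at$chain, at$resno,
          ifelse(nzchar(at$inscode), at$inscode, " "),
          xyz[, 1], xyz[, 2], xyz[, 3], at$occupancy, at$b, at$element)
}

#' Write a structure model as PDB
#'
#' Coordinates are written at 3-decimal precision in fixed PDB columns;
#' occupancancies, altloc tags and deuterium element symbols are preserved so
#' the file re-reads to an identical atom set. Multi-frame models are written
#' as MODEL/ENDMDL blocks.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  if (n_atoms(model) == 0L) stop("write_structure(): empty model", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$cell))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       model$cell[1], model$cell[2], model$cell[3],
                       model$cell[4], model$cell[5], model$cell[6],
                       if (is.null(model$spacegroup)) "P 1" else model$spacegroup), con)
  nfr <- n_frames(model)
  for (f in seq_len(nfr)) {
    if (nfr > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(.fmt_pdb_line(model$atoms, coords(model, f)), con)
    if (nfr > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by a textual expression
#'
#' Expressions are conjunctions of clauses joined by `and`:
#' `chain <id>`, `resname <name[,name...]>`, `resno <n|n:m[,...]>`,
#' `name <atom[,atom...]>`, `element <sym[,sym...]>`, `altloc <tag>`,
#' `protein`, `hetero`. Following standard PDB semantics, atoms with a blank
#' altloc belong to every conformer, so an `altloc A` clause retains
#' blank-altloc atoms as well as tag-A atoms.
#'
#' @param model a [structure_model()].
#' @param expr selection expression string.
#' @param on_missing `"warn"` (empty selection warns) or `"error"`.
#' @return integer atom indices, in atom-table order (order-stable).
#' @export
select_atoms <- function(model, expr, on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  clauses <- trimws(strsplit(expr, "\\band\\b")[[1]])
  clauses <- clauses[nzchar(clauses)]
  if (!length(clauses)) stop("empty selection expression", call. = FALSE)
  for (cl in clauses) {
    tok <- strsplit(cl, "\\s+")[[1]]
    kw <- tolower(tok[1])
    val <- if (length(tok) > 1L) paste(tok[-1], collapse = "") else ""
    keep <- keep & switch(kw,
      chain   = at$chain %in% strsplit(val, ",")[[1]],
      resname = at$resname %in% strsplit(val, ",")[[1]],
      name    = at$name %in% strsplit(val, ",")[[1]],
      element = toupper(at$element) %in% toupper(strsplit(val, ",")[[1]]),
      altloc  = at$altloc == "" | at$altloc %in% strsplit(val, ",")[[1]],
      resno   = {
        parts <- strsplit(val, ",")[[1]]
        nums <- unlist(lapply(parts, function(p) {
          if (grepl(":", p)) {
            rng <- as.integer(strsplit(p, ":")[[1]])
            seq(rng[1], rng[2])
          } else as.integer(p)
        }))
        at$resno %in% nums
      },
      protein = !at$hetatm,
      hetero  = at$hetatm,
      stop("unknown selection keyword: ", kw, call. = FALSE))
  }
  idx <- which(keep)
  if (!length(idx)) {
    msg <- paste0("selection '", expr, "' matches no atoms")
    if (on_missing == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  idx
}

#' Read a conformational ensemble
#'
#' Accepts a multi-model PDB file or a plain frame table (one row per atom
#' per frame, columns `frame, chain, resno, resname, name, altloc, x, y, z`;
#' comma- or whitespace-delimited). The atom set must be constant across
#' frames; frames are ordered by frame index / model number.
#'
#' @param path file path.
#' @param format `"auto"`, `"pdb"` or `"frame-table"`.
#' @return a [structure_model()] with >= 1 frames.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "frame-table")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "frame-table"
  if (format == "pdb") return(read_structure(path, "pdb"))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           colClasses = c(chain = "character", resname = "character",
                                          name = "character", altloc = "character"))
  need <- c("frame", "chain", "resno", "resname", "name", "altloc", "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("frame table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  tab$altloc[is.na(tab$altloc)] <- ""
  frames <- sort(unique(tab$frame))
  ref <- tab[tab$frame == frames[1], , drop = FALSE]
  key0 <- paste(ref$chain, ref$resno, ref$name, ref$altloc, sep = "|")
  arr <- array(NA_real_, dim = c(nrow(ref), 3L, length(frames)))
  for (i in seq_along(frames)) {
    fr <- tab[tab$frame == frames[i], , drop = FALSE]
    key <- paste(fr$chain, fr$resno, fr$name, fr$altloc, sep = "|")
    if (nrow(fr) != nrow(ref) || !setequal(key, key0)) {
      missing_atom <- setdiff(key0, key)
      stop(sprintf("frame %s has an inconsistent atom set (missing: %s)",
                   frames[i], paste(missing_atom, collapse = ", ")), call. = FALSE)
    }
    arr[, , i] <- as.matrix(fr[match(key0, key), c("x", "y", "z")])
  }
  atoms <- data.frame(serial = seq_len(nrow(ref)), name = ref$name, altloc = ref$altloc,
                      resname = ref$resname, chain = ref$chain, resno = ref$resno,
                      inscode = "", element = .guess_element(ref$name),
                      occupancy = 1, b = 0,
                      hetatm = !(ref$resname %in% .amino3()),
                      stringsAsFactors = FALSE)
  structure_model(atoms, arr, source = path)
}

.amino3 <- function() c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                        "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                        "THR", "TRP", "TYR", "VAL")

#' Write an ensemble as a frame table
#'
#' @param model a [structure_model()].
#' @param path output CSV path.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(model, path, digits = 4L) {
  at <- model$atoms
  nfr <- n_frames(model)
  rows <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    xyz <- round(coords(model, f), digits)
    rows[[f]] <- data.frame(frame = f, chain = at$chain, resno = at$resno,
                            resname = at$resname, name = at$name, altloc = at$altloc,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand a residue's alternate conformations
#'
#' Returns one complete atom-index set per altloc tag; blank-altloc atoms are
#' shared by (duplicated into) every conformer, following standard PDB
#' semantics.
#'
#' @param model a [structure_model()].
#' @param sel atom indices to expand (e.g. one residue).
#' @return named list of integer index vectors, one per altloc tag (a single
#'   `""` entry if the selection has no alternate conformations).
#' @export
altloc_expand <- function(model, sel) {
  alt <- model$atoms$altloc[sel]
  tags <- sort(setdiff(unique(alt), ""))
  if (!length(tags)) return(list(`_` = sel))
  out <- lapply(tags, function(tg) sel[alt == "" | alt == tg])
  names(out) <- tags
  out
}
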