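# One-bond carbon-carbon connectivity for the 20 standard residue types,
# BMRB/IUPAC atom nomenclature.  Backbone C' is bonded to CA; sidechain
# carbonyls (Asp CG, Glu CD, Asn CG, Gln CD) are included via their
# topology.  Only carbon pairs appear: C-N and C-S bonds carry no 1J-CC DQ
# resonance.
.aa_cc_bonds <- list(
  ALA = list(c("CA", "C"), c("CA", "CB")),
  ARG = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD")),
  ASN = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG")),
  ASP = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG")),
  CYS = list(c("CA", "C"), c("CA", "CB")),
  GLN = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD")),
  GLU = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD")),
  GLY = list(c("CA", "C")),
  HIS = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD2")),
  ILE = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"),
             c("CG1", "CD1")),
  LEU = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
             c("CG", "CD2")),
  LYS = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
             c("CD", "CE")),
  MET = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG")),
  PHE = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
             c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
             c("CE1", "CZ"), c("CE2", "CZ")),
  PRO = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD")),
  SER = list(c("CA", "C"), c("CA", "CB")),
  THR = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG2")),
  TRP = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
             c("CG", "CD2"), c("CD2", "CE2"), c("CD2", "CE3"),
             c("CE2", "CZ2"), c("CZ2", "CH2"), c("CH2", "CZ3"),
             c("CZ3", "CE3")),
  TYR = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
             c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
             c("CE1", "CZ"), c("CE2", "CZ")),
  VAL = list(c("CA", "C"), c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"))
)

.aa_three_to_one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                      GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                      LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                      SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# aliases occasionally seen in assignment tables -> BMRB/IUPAC names
.atom_aliases <- c("C'" = "C", "CO" = "C")

# split an NMR-STAR data line into tokens, honouring quoted values
.star_tokens <- function(line) {
  line <- sub("\\s*#.*$", "", line)
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

#' Parse chemical-shift assignments from an NMR-STAR file
#'
#' Minimal NMR-STAR 3.x reader scoped to the atom chemical-shift loop
#' (`_Atom_chem_shift.*` tags): no R package in this stack reads NMR-STAR,
#' so the loop tokenizer is implemented here.  Only carbon and nitrogen
#' assignments are retained (the DQ enumeration needs carbons; nitrogens
#' are kept for bond bookkeeping).  Duplicate (residue, atom) rows are an
#' error.
#'
#' @param path Path to an NMR-STAR file with an atom chemical-shift loop.
#' @return An `assignment_table` data frame with columns `residue`
#'   (number), `residue_type` (3-letter code), `atom`, `atom_type`
#'   (`"C"`/`"N"`) and `shift` (ppm).
#' @export
parse_assignments <- function(path) {
  if (!file.exists(path)) stop("cannot read NMR-STAR file: ", path)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  repeat {
    while (i <= n && !grepl("^\\s*loop_\\s*$", lines[i])) i <- i + 1L
    if (i > n) stop("no _Atom_chem_shift loop found in ", path)
    j <- i + 1L
    tags <- character(0)
    while (j <= n && grepl("^\\s*_", lines[j])) {
      tags <- c(tags, trimws(lines[j])); j <- j + 1L
    }
    if (any(grepl("_Atom_chem_shift\\.", tags))) break
    i <- j
  }
  want <- function(suffix) {
    hit <- grep(paste0("\\.", suffix, "$"), tags)
    if (length(hit) != 1L)
      stop("malformed chemical-shift loop near line ", i,
           ": tag _Atom_chem_shift.", suffix, " not found")
    hit
  }
  cols <- c(residue = want("Comp_index_ID"), type = want("Comp_ID"),
            atom = want("Atom_ID"), atom_type = want("Atom_type"),
            shift = want("Val"))
  rows <- list()
  k <- j
  while (k <= n) {
    ln <- trimws(lines[k])
    if (ln == "stop_" || grepl("^(loop_|save_)", ln)) break
    tok <- .star_tokens(lines[k])
    if (length(tok) > 0L) {
      if (length(tok) < length(tags))
        stop("malformed NMR-STAR data row at line ", k, ": '", ln, "'")
      rows[[length(rows) + 1L]] <- tok[cols]
    }
    k <- k + 1L
  }
  if (length(rows) == 0L) stop("empty chemical-shift loop in ", path)
  m <- do.call(rbind, rows)
  atom <- m[, 3]
  atom <- ifelse(atom %in% names(.atom_aliases), .atom_aliases[atom], atom)
  tab <- data.frame(residue = as.integer(m[, 1]),
                    residue_type = toupper(m[, 2]),
                    atom = atom,
                    atom_type = toupper(m[, 4]),
                    shift = as.numeric(m[, 5]))
  tab <- tab[tab$atom_type %in% c("C", "N"), ]
  dup <- duplicated(tab[, c("residue", "atom")])
  if (any(dup))
    stop("duplicate assignment for atom(s): ",
         paste(unique(paste0(tab$residue_type[dup], tab$residue[dup], ":",
                             tab$atom[dup])), collapse = ", "))
  rownames(tab) <- NULL
  class(tab) <- c("assignment_table", "data.frame")
  tab
}

#' Enumerate 1J-CC double-quantum resonances
#'
#' For every directly bonded carbon pair (standard residue topology) with
#' both shifts assigned, emits the two double-quantum/single-quantum peaks
#' an INADEQUATE-type experiment produces: the DQ frequency is the sum of
#' the two members' shifts and each member contributes one peak in the SQ
#' dimension.  Pairs with a missing member are skipped and counted.
#'
#' @param table An [parse_assignments()] result (or any data frame with
#'   columns `residue`, `residue_type`, `atom`, `shift`).
#' @return A `dq_peaks` data frame with columns `residue`, `residue_type`,
#'   `pair_label` (e.g. `"A9CA-CB"`), `member_atom`, `dq_ppm`, `sq_ppm`,
#'   ordered by residue, pair, member.  Skipped pairs are reported in
#'   `attr(, "skipped")`.
#' @export
enumerate_dq <- function(table) {
  stopifnot(all(c("residue", "residue_type", "atom", "shift") %in%
                  names(table)))
  carbons <- table[substr(table$atom, 1, 1) == "C" &
                     (is.null(table$atom_type) | table$atom_type != "N"), ]
  peaks <- list(); skipped <- list()
  for (res in unique(carbons$residue)) {
    sub <- carbons[carbons$residue == res, ]
    rtype <- sub$residue_type[1]
    bonds <- .aa_cc_bonds[[rtype]]
    if (is.null(bonds)) {
      warning("unknown residue type '", rtype, "' at residue ", res,
              "; skipped")
      next
    }
    code <- .aa_three_to_one[[rtype]]
    for (b in bonds) {
      sa <- sub$shift[sub$atom == b[1]]
      sb <- sub$shift[sub$atom == b[2]]
      if (length(sa) == 0L || length(sb) == 0L) {
        if (length(sa) + length(sb) > 0L)   # at least one member assigned
          skipped[[length(skipped) + 1L]] <- data.frame(
            residue = res, residue_type = rtype,
            pair = paste(b, collapse = "-"),
            missing_atom = if (length(sa) == 0L) b[1] else b[2])
        next
      }
      lab <- paste0(code, res, b[1], "-", b[2])
      dq <- sa + sb
      peaks[[length(peaks) + 1L]] <- data.frame(
        residue = res, residue_type = rtype, pair_label = lab,
        member_atom = b, dq_ppm = dq, sq_ppm = c(sa, sb))
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(residue = integer(0), residue_type = character(0),
               pair_label = character(0), member_atom = character(0),
               dq_ppm = numeric(0), sq_ppm = numeric(0))
  out <- out[order(out$residue, out$pair_label, out$member_atom), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(residue = integer(0), residue_type = character(0),
               pair = character(0), missing_atom = character(0))
  class(out) <- c("dq_peaks", "data.frame")
  out
}

#' Write DQ peak lists
#'
#' Writes the enumerated DQ/SQ peaks as a Sparky-style assignment list
#' (label, w1 = DQ ppm, w2 = SQ ppm) and/or a CSV twin, with a byte-stable
#' ordering (residue, then pair, then member atom).
#'
#' @param peaks An [enumerate_dq()] result (must be non-empty).
#' @param path Output file path.
#' @param format `"sparky"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_peaklists <- function(peaks, path, format = c("sparky", "csv")) {
  format <- match.arg(format)
  if (nrow(peaks) == 0L) stop("empty peak list")
  p <- peaks[order(peaks$residue, peaks$pair_label, peaks$member_atom), ]
  if (format == "sparky") {
    lines <- c(sprintf("%25s %10s %10s", "Assignment", "w1", "w2"),
               sprintf("%25s %10.3f %10.3f",
                       paste0(p$pair_label, ".", p$member_atom),
                       p$dq_ppm, p$sq_ppm))
    writeLines(lines, path)
  } else {
    utils::write.csv(
      data.frame(label = paste0(p$pair_label, ".", p$member_atom),
                 residue = p$residue, pair = p$pair_label,
                 member_atom = p$member_atom,
                 dq_ppm = p$dq_ppm, sq_ppm = p$sq_ppm),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
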