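# Atom table columns shared by every Structure. `insert` and `alt` use "" (not
# NA) for absent codes so residue keys paste cleanly; `het` marks HETATM
# records; `radius` is NA until assign_radii() is called.
.atom_cols <- c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "occ", "alt", "het", "radius")

.water_resids <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP3")

#' Construct a Structure from an atom table
#'
#' A `Structure` is the package's container for macromolecular coordinates: a
#' flat atom table (one row per atom, author chain/residue numbering, Cartesian
#' coordinates in Angstrom) plus a source identifier and model index. Chains
#' and residues are ordered as given; residue identity is the triple
#' (chain, resno, insert).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (atom name), `element`, `x`, `y`, `z`, and optionally `occ`,
#'   `alt`, `het`, `radius`. Missing optional columns are filled with defaults.
#' @param id source identifier (e.g. a PDB accession, or "synthetic").
#' @param model model index the coordinates came from.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, id = "unknown", model = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "insert", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert <- as.character(atoms$insert)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  rownames(atoms) <- NULL
  structure(list(id = id, model = as.integer(model), atoms = atoms[, .atom_cols]),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure '%s' (model %d): %d atoms, %d residues, chains: %s\n",
              x$id, x$model, nrow(a), n_residues(x),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param s a Structure
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Number of residues in a Structure
#' @param s a Structure
#' @export
n_residues <- function(s) length(unique(residue_keys(s)))

#' Per-atom residue key "chain|resno|insert"
#' @param s a Structure
#' @keywords internal
#' @export
residue_keys <- function(s) paste(s$atoms$chain, s$atoms$resno, s$atoms$insert, sep = "|")

#' Coordinates of a Structure as an n x 3 matrix
#' @param s a Structure
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Replace the coordinates of a Structure
#' @param s a Structure
#' @param xyz n x 3 matrix matching the atom count
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(s) || ncol(xyz) != 3)
    stop("coordinate matrix must be ", n_atoms(s), " x 3")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Reference to a single residue
#'
#' @param chain chain id
#' @param resno author residue number
#' @param insert insertion code ("" if none)
#' @param resid 3-letter residue name (optional, informational)
#' @export
residue_ref <- function(chain, resno, insert = "", resid = NA_character_) {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 insert = as.character(insert), resid = resid),
            class = "ResidueRef")
}

#' @export
format.ResidueRef <- function(x, ...) {
  sprintf("%s%s/%d%s", ifelse(is.na(x$resid), "", paste0(x$resid, " ")),
          x$chain, x$resno, x$insert)
}

#' @export
print.ResidueRef <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

.ref_key <- function(ref) paste(ref$chain, ref$resno, ref$insert, sep = "|")

.guess_element <- function(elety) {
  # PDB convention: element is in columns 77-78; when absent, strip digits and
  # leading whitespace from the atom name. Handle two-letter elements seen in
  # protein work.
  e <- gsub("[0-9'\\*]", "", trimws(elety))
  two <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "SE", "BR", "CU", "NI", "CD")
  # atom names like "CA" within a residue are carbon-alpha, not calcium; only
  # trust two-letter symbols for names that start at column 13 (unknowable
  # here), so default to first letter for standard organic atoms.
  first <- substr(e, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first,
         ifelse(e %in% two, e, first))
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Waters are excluded; heteroatoms are retained and tagged (`het` column);
#' hydrogens are retained if present. Alternate locations are reduced to one
#' per atom according to `altloc`.
#'
#' @param path file path
#' @param format "pdb", "mmcif", or "auto" (by extension)
#' @param model model number to extract (1-based)
#' @param altloc "highest" keeps the highest-occupancy alternate, "first" the
#'   first encountered
#' @param keep_waters retain water residues (default FALSE)
#' @return a Structure
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), model = 1L,
                           altloc = c("highest", "first"), keep_waters = FALSE) {
  format <- match.arg(format)
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  at <- switch(format, pdb = .read_pdb_atoms(path, model), mmcif = .read_mmcif_atoms(path, model))
  id <- toupper(sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE))
  s <- new_structure(at, id = id, model = model)
  if (!keep_waters) s <- .drop_waters(s)
  .filter_altloc(s, altloc)
}

.read_pdb_atoms <- function(path, model) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file '", path, "': ",
                                           conditionMessage(e)))
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod)) nmod <- 1L
  if (model < 1 || model > nmod)
    stop("model ", model, " not found in '", path, "' (", nmod, " model(s))")
  a <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  elem <- ifelse(is.na(elem) | trimws(elem) == "", .guess_element(a$elety), trimws(elem))
  data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
             resno = a$resno,
             insert = ifelse(is.na(a$insert), "", a$insert),
             resid = a$resid,
             elety = a$elety,
             element = toupper(elem),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = ifelse(is.na(a$o), 1, a$o),
             alt = ifelse(is.na(a$alt), "", a$alt),
             het = a$type == "HETATM",
             stringsAsFactors = FALSE)
}

# Minimal mmCIF reader: extracts the _atom_site loop. Values are
# whitespace-separated with '"' / "'" quoting; multi-line ';' fields do not
# occur in atom_site loops.
.read_mmcif_atoms <- function(path, model) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  tags <- character(); rows <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L; tags <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1L
      }
      if (length(tags) && all(startsWith(tags, "_atom_site."))) {
        vals <- character()
        while (j <= n && !grepl("^\\s*(loop_|_|#)", lines[j]) && nzchar(trimws(lines[j]))) {
          vals <- c(vals, scan(text = lines[j], what = character(), quiet = TRUE))
          j <- j + 1L
        }
        if (length(vals) %% length(tags) != 0)
          stop("malformed _atom_site loop in '", path, "'")
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        colnames(m) <- sub("^_atom_site\\.", "", tags)
        rows <- m
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) stop("no _atom_site loop found in '", path, "'")
  g <- function(nm, default = NA_character_) {
    if (nm %in% colnames(rows)) { v <- rows[, nm]; v[v %in% c(".", "?")] <- NA; v }
    else rep(default, nrow(rows))
  }
  modnum <- suppressWarnings(as.integer(g("pdbx_PDB_model_num", "1")))
  modnum[is.na(modnum)] <- 1L
  if (!model %in% modnum) stop("model ", model, " not found in '", path, "'")
  keep <- modnum == model
  atom_nm <- g("auth_atom_id"); lab_nm <- g("label_atom_id")
  elety <- ifelse(is.na(atom_nm), lab_nm, atom_nm)
  resid <- g("auth_comp_id"); resid[is.na(resid)] <- g("label_comp_id")[is.na(resid)]
  chain <- g("auth_asym_id"); chain[is.na(chain)] <- g("label_asym_id")[is.na(chain)]
  resno <- g("auth_seq_id"); resno[is.na(resno)] <- g("label_seq_id")[is.na(resno)]
  out <- data.frame(chain = chain, resno = suppressWarnings(as.integer(resno)),
                    insert = ifelse(is.na(g("pdbx_PDB_ins_code")), "", g("pdbx_PDB_ins_code")),
                    resid = resid, elety = elety,
                    element = toupper(ifelse(is.na(g("type_symbol")),
                                             .guess_element(elety), g("type_symbol"))),
                    x = as.numeric(g("Cartn_x")), y = as.numeric(g("Cartn_y")),
                    z = as.numeric(g("Cartn_z")),
                    occ = suppressWarnings(as.numeric(g("occupancy", "1"))),
                    alt = ifelse(is.na(g("label_alt_id")), "", g("label_alt_id")),
                    het = g("group_PDB", "ATOM") == "HETATM",
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$occ[is.na(out$occ)] <- 1
  if (!all(is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-numeric coordinates in '", path, "'")
  out
}

.drop_waters <- function(s) {
  s$atoms <- s$atoms[!(s$atoms$resid %in% .water_resids), , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

.filter_altloc <- function(s, policy) {
  a <- s$atoms
  if (!any(nzchar(a$alt))) return(s)
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[nzchar(a$alt)])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    pick <- if (policy == "highest") idx[which.max(a$occ[idx])] else idx[1]
    keep[setdiff(idx, pick)] <- FALSE
  }
  s$atoms <- a[keep, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

#' Write a Structure (or multi-frame trajectory) as PDB
#'
#' Coordinates are written at standard PDB precision (0.001 A). Chains with
#' residue numbers above 9999 are rejected (PDB fixed-width limit).
#'
#' @param s a Structure
#' @param path output path
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  if (!n_atoms(s)) stop("refusing to write an empty Structure")
  a <- s$atoms
  if (any(a$resno > 9999 | a$resno < -999))
    stop("residue numbers outside the PDB fixed-width range (-999..9999); renumber first")
  con <- file(path, "w")
  on.exit(close(con))
  .write_pdb_model(con, a)
  writeLines("END", con)
  invisible(NULL)
}

.write_pdb_model <- function(con, a) {
  serial <- seq_len(nrow(a)) %% 100000
  # atom-name column convention: names of <4 chars start in column 14 unless a
  # two-letter element occupies 13-14
  nm <- vapply(seq_len(nrow(a)), function(i) {
    e <- a$elety[i]
    if (nchar(e) >= 4) substr(e, 1, 4)
    else if (nchar(a$element[i]) == 2) sprintf("%-4s", e)
    else sprintf(" %-3s", e)
  }, character(1))
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, serial, nm,
                   substr(paste0(a$alt, " "), 1, 1),
                   sprintf("%3s", a$resid),
                   substr(paste0(a$chain, " "), 1, 1),
                   a$resno,
                   substr(paste0(a$insert, " "), 1, 1),
                   a$x, a$y, a$z, a$occ, 0, sprintf("%2s", a$element))
  writeLines(lines, con)
}

#' Select atoms from a Structure
#'
#' Filters by any combination of chain, residue number set or range, domain
#' labels (via a domain map), atom name, element, and het status. The returned
#' Structure preserves atom order. An empty result triggers a warning (not a
#' silent empty), since downstream metrics on empty selections are almost
#' always user error.
#'
#' @param s a Structure
#' @param chain chain id(s), or NULL
#' @param resno integer vector of residue numbers (use `seq` or `:` for
#'   ranges), or NULL
#' @param domain domain label(s) from `domain_map` (e.g. c("I","II","III")),
#'   or NULL
#' @param domain_map a domain map (see [domain_map()]) required when `domain`
#'   is given
#' @param elety atom name(s) (e.g. "CA"), or NULL
#' @param element element symbol(s), or NULL
#' @param het NA (keep both), TRUE (only HETATM), FALSE (only ATOM)
#' @param heavy_only drop hydrogens and deuterium
#' @return a Structure containing the matching atoms
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL, domain = NULL,
                         domain_map = NULL, elety = NULL, element = NULL,
                         het = NA, heavy_only = FALSE) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% as.integer(resno)
  if (!is.null(domain)) {
    if (is.null(domain_map)) stop("domain selection requires a domain_map")
    bad <- setdiff(domain, names(domain_map$domains))
    if (length(bad)) stop("domain label(s) not in map: ", paste(bad, collapse = ", "))
    in_dom <- rep(FALSE, nrow(a))
    for (d in domain) {
      iv <- domain_map$domains[[d]]
      in_dom <- in_dom | (a$resno >= iv[1] & a$resno <= iv[2])
    }
    keep <- keep & in_dom
  }
  if (!is.null(elety)) keep <- keep & trimws(a$elety) %in% elety
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.na(het)) keep <- keep & (a$het == het)
  if (heavy_only) keep <- keep & !(a$element %in% c("H", "D"))
  out <- s
  out$atoms <- a[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  if (!nrow(out$atoms)) warning("selection matched no atoms in '", s$id, "'")
  out
}

#' Domain map for a receptor ectodomain
#'
#' Assigns inclusive author-numbering intervals to ectodomain domains I-V.
#' Intervals must not overlap.
#'
#' @param receptor receptor name
#' @param ... named intervals, e.g. `I = c(1, 165)`
#' @export
domain_map <- function(receptor, ...) {
  doms <- list(...)
  if (!length(doms)) stop("at least one domain interval required")
  bad <- setdiff(names(doms), c("I", "II", "III", "IV", "V"))
  if (length(bad)) stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  doms <- lapply(doms, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2 || iv[1] > iv[2]) stop("interval must be c(start, end)")
    iv
  })
  ivs <- do.call(rbind, doms)
  o <- order(ivs[, 1])
  if (any(ivs[o, 1][-1] <= ivs[o, 2][-nrow(ivs)]))
    stop("domain intervals overlap")
  structure(list(receptor = receptor, domains = doms), class = "DomainMap")
}

#' @export
print.DomainMap <- function(x, ...) {
  cat("DomainMap for", x$receptor, "\n")
  for (d in names(x$domains))
    cat(sprintf("  %-3s %d-%d\n", d, x$domains[[d]][1], x$domains[[d]][2]))
  invisible(x)
}

#' Load domain maps from the shipped (or a user) JSON config
#'
#' The package ships default ectodomain domain intervals in mature receptor
#' numbering. The EGFR intervals (I 1-165, II 166-310, III 311-480, IV
#' 481-620) follow the conventional subdomain boundaries of the mature
#' ectodomain; the Her2 and Her3 maps use the same mature-numbering intervals,
#' which is adequate at domain granularity for close homologs but can be
#' overridden with an alignment-derived config for residue-exact work.
#'
#' @param path JSON config path; default is the shipped config
#' @return named list of DomainMap objects
#' @export
load_domain_maps <- function(path = system.file("extdata", "domain_maps.json",
                                                package = "ectodimer")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(cfg), function(rec) {
    do.call(domain_map, c(list(receptor = rec),
                          lapply(as.data.frame(cfg[[rec]]), function(iv) iv)))
  })
  names(out) <- names(cfg)
  out
}

#' Fill missing residues in a structure from a homologous donor
#'
#' The donor is rigidly superposed onto the target over the C-alpha atoms of
#' an anchor window (residues present in both), then donor residues covering
#' `range` that are absent from the target are copied in. Geometry inside the
#' filled stretch is donor-local; only the rigid placement comes from the
#' anchor fit.
#'
#' @param target Structure with a gap
#' @param donor Structure containing the residues to transplant
#' @param range integer vector of residue numbers to fill
#' @param anchor integer vector of residue numbers to superpose on (>= 3
#'   shared C-alpha required)
#' @param chain chain id in both structures (default: first chain of target)
#' @return Structure with the gap filled; attribute `anchor_rmsd` records the
#'   fit quality
#' @export
merge_missing_residues <- function(target, donor, range, anchor, chain = NULL) {
  stopifnot(inherits(target, "Structure"), inherits(donor, "Structure"))
  if (is.null(chain)) chain <- target$atoms$chain[1]
  range <- as.integer(range); anchor <- as.integer(anchor)
  have <- unique(target$atoms$resno[target$atoms$chain == chain])
  missing <- setdiff(range, have)
  if (!length(missing)) {
    warning("range already present in target; returning it unchanged")
    return(target)
  }
  don_have <- unique(donor$atoms$resno[donor$atoms$chain %in% donor$atoms$chain])
  if (!all(range %in% donor$atoms$resno))
    stop("donor lacks residues ", paste(setdiff(range, donor$atoms$resno), collapse = ","),
         " of the requested range")
  tca <- select_atoms(target, chain = chain, resno = anchor, elety = "CA")
  dca <- select_atoms(donor, resno = anchor, elety = "CA")
  shared <- intersect(tca$atoms$resno, dca$atoms$resno)
  if (length(shared) < 3) stop("anchor window has fewer than 3 shared residues")
  tm <- coords(select_atoms(target, chain = chain, resno = shared, elety = "CA"))
  dm <- coords(select_atoms(donor, resno = shared, elety = "CA"))
  fit <- kabsch_superpose(dm, tm)
  donor_placed <- set_coords(donor, apply_transform(fit$transform, coords(donor)))
  add <- donor_placed$atoms[donor_placed$atoms$resno %in% missing, , drop = FALSE]
  add$chain <- chain
  out <- target
  merged <- rbind(out$atoms, add)
  # keep residues ordered within the chain
  ord <- order(match(merged$chain, unique(merged$chain)), merged$resno, merged$insert)
  out$atoms <- merged[ord, , drop = FALSE]
  rownames(out$atoms) <- NULL
  if (anyDuplicated(paste(residue_keys(out), out$atoms$elety)))
    stop("merge produced duplicate atoms")
  attr(out, "anchor_rmsd") <- fit$rmsd
  out
}
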