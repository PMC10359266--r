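#' @importFrom stats prcomp setNames dist
#' @importFrom utils head read.delim write.table
NULL

# Atom-table columns every pore_structure carries, in this order.
.ATOM_COLS <- c("serial", "name", "element", "x", "y", "z",
                "occ", "altloc", "chain", "resno", "icode", "comp", "hetero")

.STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

#' Default entity classification table
#'
#' Maps chemical component codes to entity classes. The table is deliberately
#' small and extensible: pass a modified copy to [classify_entities()] to add
#' site-specific component codes (e.g. alternative phospholipid models).
#'
#' @return A named list of character vectors of component codes with elements
#'   `water`, `monatomic_ion`, `phospholipid`, `sterol`, `retinal`, `protein`.
#' @export
entity_classes <- function() {
  list(
    water         = c("HOH", "DOD", "WAT"),
    monatomic_ion = c("NA", "K", "CL", "MG", "ZN", "CA", "IOD", "BR", "CS", "RB"),
    # PEE is the dioleoylphosphatidylethanolamine component; common PE/PC models kept too
    phospholipid  = c("PEE", "POP", "POPE", "POPC", "PC1", "3PE", "PTY", "LPP", "PGV"),
    sterol        = c("CLR", "CHS", "Y01"),
    retinal       = c("RET", "LYR"),
    protein       = .STD_AA
  )
}

res_key <- function(chain, resno, icode = "", comp = NULL) {
  ic <- ifelse(is.na(icode) | icode == " ", "", icode)
  k <- sprintf("%s:%s%s", chain, resno, ic)
  if (!is.null(comp)) k <- sprintf("%s:%s", k, comp)
  k
}

# element symbol from a PDB atom name when the element column is absent
.guess_element <- function(name, comp) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  # two-letter elements common in models; monatomic ions carry their own comp code
  el[two %in% c("FE", "ZN", "MG", "MN", "CU", "NI", "BR", "SE")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "CU", "NI", "BR", "SE")]
  ion <- comp %in% entity_classes()$monatomic_ion & nm == comp
  el[ion] <- comp[ion]
  el
}

.new_structure <- function(id, atoms, assembly = NULL) {
  atoms <- atoms[, .ATOM_COLS]
  rownames(atoms) <- NULL
  if (is.null(assembly)) {
    ch <- unique(atoms$chain[!atoms$hetero])
    if (length(ch) == 0L) ch <- unique(atoms$chain)
    assembly <- setNames(seq_along(ch), ch)
    extra <- setdiff(unique(atoms$chain), ch)
    if (length(extra)) assembly <- c(assembly, setNames(rep(NA_integer_, length(extra)), extra))
  }
  structure(list(id = id, atoms = atoms, assembly = assembly),
            class = "pore_structure")
}

#' Parse a macromolecular structure file
#'
#' Reads an atomic model in PDB or mmCIF format into a `pore_structure`: a flat
#' atom table (author residue numbering preserved) plus a chain-to-protomer
#' assembly map. Zero-occupancy atoms are dropped. For alternate-location
#' groups only the conformer with the highest occupancy is retained (ties
#' broken by alphabetically first altloc identifier).
#'
#' @param path Path to a coordinate file.
#' @param dialect `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param id Structure identifier; defaults to the file stem.
#' @return An object of class `pore_structure` with elements `id`, `atoms`
#'   (data frame with columns serial, name, element, x, y, z, occ, altloc,
#'   chain, resno, icode, comp, hetero) and `assembly` (named integer vector,
#'   chain to protomer index).
#' @export
parse_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                            id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    if (dialect == "mmcif") bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", dialect, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in ", path)
  atoms <- data.frame(
    serial  = as.integer(a$eleno),
    name    = as.character(a$elety),
    element = as.character(a$elesy),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
    occ     = ifelse(is.na(a$o), 1, as.numeric(a$o)),
    altloc  = ifelse(is.na(a$alt) | a$alt == "", "", as.character(a$alt)),
    chain   = ifelse(is.na(a$chain), "A", as.character(a$chain)),
    resno   = as.integer(a$resno),
    icode   = ifelse(is.na(a$insert) | a$insert == "", "", as.character(a$insert)),
    comp    = as.character(a$resid),
    hetero  = a$type == "HETATM",
    stringsAsFactors = FALSE)
  bad <- is.na(atoms$element) | atoms$element == ""
  if (any(bad)) atoms$element[bad] <- .guess_element(atoms$name[bad], atoms$comp[bad])
  atoms <- atoms[atoms$occ > 0, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty model (no atoms with positive occupancy) in ", path)
  atoms <- .resolve_altloc(atoms)
  .new_structure(id, atoms)
}

# per residue keep the altloc with highest total occupancy (tie: first alphabetically)
.resolve_altloc <- function(atoms) {
  if (!any(atoms$altloc != "")) return(atoms)
  rid <- res_key(atoms$chain, atoms$resno, atoms$icode)
  keep <- rep(TRUE, nrow(atoms))
  for (r in unique(rid[atoms$altloc != ""])) {
    i <- which(rid == r & atoms$altloc != "")
    occ <- tapply(atoms$occ[i], atoms$altloc[i], sum)
    best <- names(occ)[order(-occ, names(occ))][1L]
    keep[i[atoms$altloc[i] != best]] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- ""
  atoms
}

#' @export
print.pore_structure <- function(x, ...) {
  cls <- classify_entities(x, warn = FALSE)
  cat(sprintf("pore_structure '%s': %d atoms, %d residues, %d chain(s)\n",
              x$id, nrow(x$atoms), length(cls), length(unique(x$atoms$chain))))
  print(table(cls))
  invisible(x)
}

#' Write a structure as a PDB file
#'
#' Minimal fixed-width PDB writer. Output is byte-deterministic for a given
#' structure, which the fixture generator relies on.
#'
#' @param s A `pore_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  rec <- ifelse(a$hetero, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
               sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  lines <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, nm,
                   ifelse(a$altloc == "", " ", a$altloc),
                   a$comp, a$chain, a$resno,
                   ifelse(a$icode == "", " ", a$icode),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Residue index table of a structure
#'
#' @param s A `pore_structure`.
#' @return Data frame with one row per residue: `key`, `chain`, `resno`,
#'   `icode`, `comp`, `hetero`, in file order.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- res_key(a$chain, a$resno, a$icode, a$comp)
  i <- !duplicated(key)
  data.frame(key = key[i], chain = a$chain[i], resno = a$resno[i],
             icode = a$icode[i], comp = a$comp[i], hetero = a$hetero[i],
             stringsAsFactors = FALSE)
}

#' Classify every residue into an entity class
#'
#' Assigns each residue exactly one label from `protein`, `water`,
#' `monatomic_ion`, `phospholipid`, `sterol`, `retinal`, `other_het`. Any
#' heteroatom residue consisting of a single atom that matches no table entry
#' is treated as a monatomic ion; unknown multi-atom het groups fall through
#' to `other_het` with a warning.
#'
#' @param s A `pore_structure`.
#' @param classes Classification table, see [entity_classes()].
#' @param warn Warn on unknown het components? Default `TRUE`.
#' @return Named character vector: residue key (`chain:resno:comp`) to class.
#' @export
classify_entities <- function(s, classes = entity_classes(), warn = TRUE) {
  rt <- residue_table(s)
  a <- s$atoms
  natoms <- table(res_key(a$chain, a$resno, a$icode, a$comp))
  cls <- rep("other_het", nrow(rt))
  cls[rt$comp %in% classes$protein]       <- "protein"
  cls[rt$comp %in% classes$water]         <- "water"
  cls[rt$comp %in% classes$retinal]       <- "retinal"
  cls[rt$comp %in% classes$sterol]        <- "sterol"
  cls[rt$comp %in% classes$phospholipid]  <- "phospholipid"
  cls[rt$comp %in% classes$monatomic_ion] <- "monatomic_ion"
  single <- cls == "other_het" & rt$hetero & as.integer(natoms[rt$key]) == 1L
  cls[single] <- "monatomic_ion"
  if (warn && any(cls == "other_het")) {
    warning("unclassified het component(s): ",
            paste(unique(rt$comp[cls == "other_het"]), collapse = ", "),
            call. = FALSE)
  }
  setNames(cls, rt$key)
}

# protomer index per residue; het residues go to the nearest protein chain
.residue_protomer <- function(s, cls) {
  rt <- residue_table(s)
  a <- s$atoms
  akey <- res_key(a$chain, a$resno, a$icode, a$comp)
  prot_keys <- rt$key[cls[rt$key] %in% c("protein", "retinal")]
  prot_atoms <- a[akey %in% prot_keys, ]
  pid <- setNames(rep(NA_integer_, nrow(rt)), rt$key)
  direct <- rt$key %in% prot_keys
  pid[rt$key[direct]] <- unname(s$assembly[rt$chain[direct]])
  if (any(!direct) && nrow(prot_atoms)) {
    pm <- as.matrix(prot_atoms[, c("x", "y", "z")])
    pp <- unname(s$assembly[prot_atoms$chain])
    for (k in rt$key[!direct]) {
      hm <- as.matrix(a[akey == k, c("x", "y", "z"), drop = FALSE])
      d2 <- outer(rowSums(hm^2), rowSums(pm^2), "+") - 2 * hm %*% t(pm)
      pid[k] <- pp[which.min(apply(d2, 2, min))]
    }
  }
  pid
}

#' Count residues per entity class
#'
#' @param s A `pore_structure`.
#' @param scope `"all"` for the whole deposited model, or `"protomer"` to
#'   restrict to one protomer. With protomer scope, het residues (waters, ions,
#'   lipids) are assigned to the protomer of the nearest protein chain by
#'   minimum interatomic distance.
#' @param protomer Protomer index (required for `scope = "protomer"`).
#' @param classes Classification table, see [entity_classes()].
#' @return Named integer vector of counts over all entity classes.
#' @export
entity_census <- function(s, scope = c("all", "protomer"), protomer = NULL,
                          classes = entity_classes()) {
  scope <- match.arg(scope)
  lvls <- c("protein", "water", "monatomic_ion", "phospholipid", "sterol",
            "retinal", "other_het")
  if (nrow(s$atoms) == 0L) return(setNames(integer(length(lvls)), lvls))
  cls <- classify_entities(s, classes, warn = FALSE)
  if (scope == "protomer") {
    if (is.null(protomer)) stop("protomer index required for scope = 'protomer'")
    if (!protomer %in% s$assembly) stop("invalid protomer index: ", protomer)
    pid <- .residue_protomer(s, cls)
    cls <- cls[names(pid)[!is.na(pid) & pid == protomer]]
  }
  tab <- table(factor(cls, levels = lvls))
  setNames(as.integer(tab), lvls)
}

#' Extract one protomer as a structure
#'
#' Keeps the protein chain(s) of the given protomer index together with the
#' het residues (waters, ions, lipids, retinal) assigned to it by nearest
#' protein-chain distance.
#'
#' @inheritParams entity_census
#' @return A `pore_structure`.
#' @export
select_protomer <- function(s, protomer = 1L) {
  if (!protomer %in% s$assembly) stop("invalid protomer index: ", protomer)
  cls <- classify_entities(s, warn = FALSE)
  pid <- .residue_protomer(s, cls)
  keep_keys <- names(pid)[!is.na(pid) & pid == protomer]
  a <- s$atoms
  akey <- res_key(a$chain, a$resno, a$icode, a$comp)
  .new_structure(sprintf("%s_p%d", s$id, protomer), a[akey %in% keep_keys, ],
                 assembly = s$assembly[s$assembly == protomer & !is.na(s$assembly)])
}

#' One-letter amino-acid sequence of a structure
#'
#' @param s A `pore_structure`.
#' @param chain Chain identifier; default first protein chain.
#' @return Named character vector of one-letter codes, names are residue
#'   numbers (author numbering), in sequence order.
#' @export
structure_sequence <- function(s, chain = NULL) {
  rt <- residue_table(s)
  rt <- rt[rt$comp %in% .STD_AA, ]
  if (nrow(rt) == 0L) stop("no protein residues in structure ", s$id)
  if (is.null(chain)) chain <- rt$chain[1L]
  rt <- rt[rt$chain == chain, ]
  rt <- rt[order(rt$resno, rt$icode), ]
  aa1 <- setNames(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                    "P","S","T","W","Y","V"), .STD_AA)
  setNames(unname(aa1[rt$comp]), rt$resno)
}

#' Write an entity census as a tab-separated report
#'
#' @param census Named integer vector from [entity_census()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  write.table(data.frame(class = names(census), count = as.integer(census)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
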