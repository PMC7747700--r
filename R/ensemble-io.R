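#' @importFrom stats rnorm runif sd setNames median optim coef resid dist
#'   quantile t.test
#' @importFrom utils read.table write.table head tail modifyList
NULL

# Residue names treated as standard protein residues by classify_entities().
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Modified residues commonly deposited as HETATM; flagged when classified
# as ligand so the user can reassign them.
.modified_aa <- c("MSE", "SEP", "TPO", "PTR", "CSO", "HYP", "MLY", "PCA")

#' Construct a structural ensemble
#'
#' An `ensemble` holds an ordered set of coordinate models (crystallographic
#' ensemble-refinement models or trajectory frames) that share one atom
#' topology. Coordinates are stored as an `n_atoms x 3 x n_models` array and
#' per-model B-factors as an `n_atoms x n_models` matrix, so per-model
#' statistics (interaction persistence, RMSF, B-factor ratios) are direct
#' array operations.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `altloc`, `occupancy`, `type`
#'   (`"ATOM"`/`"HETATM"`). One row per atom of the shared topology.
#' @param coords numeric array `n_atoms x 3 x n_models` (Angstrom).
#' @param bfactor numeric matrix `n_atoms x n_models` (Angstrom^2), or a
#'   vector recycled across models.
#' @param model_ids integer ids, one per model.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(atoms, coords, bfactor = NULL, model_ids = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- nrow(atoms)
  n_models <- dim(coords)[3]
  if (dim(coords)[1] != n_atoms)
    stop("coords first dimension must match nrow(atoms)")
  if (is.null(bfactor)) bfactor <- matrix(0, n_atoms, n_models)
  if (is.vector(bfactor)) bfactor <- matrix(bfactor, n_atoms, n_models)
  if (is.null(model_ids)) model_ids <- seq_len(n_models)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique within a model")
  structure(
    list(atoms = atoms, coords = coords, bfactor = bfactor,
         model_ids = as.integer(model_ids)),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d model(s), %d atoms\n", n_models(x), nrow(x$atoms)))
  cls <- classify_entities(x, quiet = TRUE)
  cat(sprintf("  protein %d | ligand %d | water %d atoms\n",
              length(cls$protein), length(cls$ligand), length(cls$water)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param e ensemble.
#' @return integer.
#' @export
n_models <- function(e) dim(e$coords)[3]

#' Canonical topology key of an ensemble
#'
#' `(chain, resid, name, altloc)` tuples in file order; identical for every
#' model by construction.
#' @param e ensemble.
#' @return character vector, one entry per atom.
#' @export
topology_key <- function(e) {
  with(e$atoms, paste(chain, resid, name, altloc, sep = "|"))
}

#' Extract one model from an ensemble
#' @param e ensemble.
#' @param i model index (1-based position, not model id).
#' @return A `structure_model`: list with `atoms`, `coords` (n x 3 matrix),
#'   `bfactor` (vector), `model_id`.
#' @export
get_model <- function(e, i) {
  stopifnot(i >= 1, i <= n_models(e))
  structure(
    list(atoms = e$atoms, coords = e$coords[, , i, drop = TRUE],
         bfactor = e$bfactor[, i], model_id = e$model_ids[i]),
    class = "structure_model"
  )
}

# Split raw PDB lines into per-model chunks of ATOM/HETATM lines.
# Returns list of character vectors plus the global line numbers.
.split_models <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    idx <- grep("^(ATOM|HETATM)", lines)
    return(list(list(lines = lines[idx], lineno = idx)))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records")
  lapply(seq_along(model_starts), function(k) {
    rng <- seq(model_starts[k] + 1L, model_ends[k] - 1L)
    idx <- rng[grepl("^(ATOM|HETATM)", lines[rng])]
    list(lines = lines[idx], lineno = idx)
  })
}

#' Read a multi-model PDB file into an ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one model; a file without `MODEL`
#' records yields a single-model ensemble. `HETATM` records (ligands,
#' waters) are retained, as are alternate-location indicators and
#' occupancies. All models must share one topology (atom count and
#' `(chain, resid, name, altloc)` ordering); per-model B-factors are kept.
#'
#' @param path PDB file path.
#' @return An [ensemble()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  chunks <- .split_models(lines)

  # coordinate fields must be numeric; report offending line on failure
  for (ch in chunks) {
    for (j in seq_along(ch$lines)) {
      xyz <- suppressWarnings(as.numeric(c(
        substr(ch$lines[j], 31, 38), substr(ch$lines[j], 39, 46),
        substr(ch$lines[j], 47, 54)
      )))
      if (any(is.na(xyz)))
        stop(sprintf("unparseable coordinate field at line %d", ch$lineno[j]))
    }
  }

  parse_chunk <- function(ch) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(c(ch$lines, "END"), tmp)
    pdb <- suppressWarnings(
      bio3d::read.pdb(tmp, rm.alt = FALSE, rm.insert = FALSE, verbose = FALSE)
    )
    pdb$atom
  }
  tabs <- lapply(chunks, parse_chunk)

  key <- function(at) paste(at$chain, at$resno, at$elety, at$alt, sep = "|")
  ref <- tabs[[1]]
  for (m in seq_along(tabs)) {
    if (nrow(tabs[[m]]) != nrow(ref) || !identical(key(tabs[[m]]), key(ref)))
      stop(sprintf("inconsistent atom topology across models: model %d differs", m))
  }

  n_atoms <- nrow(ref)
  n_mod <- length(tabs)
  coords <- array(NA_real_, c(n_atoms, 3L, n_mod))
  bf <- matrix(NA_real_, n_atoms, n_mod)
  for (m in seq_len(n_mod)) {
    coords[, , m] <- as.matrix(tabs[[m]][, c("x", "y", "z")])
    bf[, m] <- tabs[[m]]$b
  }
  clean <- function(v, fill = "") ifelse(is.na(v), fill, v)
  atoms <- data.frame(
    serial = ref$eleno,
    name = ref$elety,
    element = clean(ref$elesy),
    resname = ref$resid,
    resid = ref$resno,
    chain = clean(ref$chain, "A"),
    altloc = clean(ref$alt),
    occupancy = ifelse(is.na(ref$o), 1, ref$o),
    type = ref$type,
    stringsAsFactors = FALSE
  )
  ensemble(atoms, coords, bf)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Writes one `MODEL`/`ENDMDL` block per model in PDB v3.3 fixed columns
#' (coordinates at 3 decimals, occupancy/B at 2). Re-reading the file
#' reproduces identifiers exactly and numerics at format precision.
#'
#' @param e ensemble.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(e, path) {
  con <- tryCatch(file(path, "w"), error = function(err)
    stop("cannot open for writing: ", path))
  close(con)
  at <- e$atoms
  body <- character(0)
  for (m in seq_len(n_models(e))) {
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(
      file = tmp, xyz = as.vector(t(e$coords[, , m])),
      type = at$type, resno = at$resid, resid = at$resname,
      eleno = at$serial, elety = at$name, chain = at$chain,
      alt = ifelse(at$altloc == "", NA, at$altloc),
      o = at$occupancy, b = e$bfactor[, m], elesy = at$element,
      end = FALSE
    )
    rec <- readLines(tmp, warn = FALSE)
    unlink(tmp)
    rec <- rec[grepl("^(ATOM|HETATM|TER)", rec)]
    body <- c(body, sprintf("MODEL     %4d", e$model_ids[m]), rec, "ENDMDL")
  }
  writeLines(c(body, "END"), path)
  invisible(path)
}

#' Read a per-frame XYZ coordinate table as an ensemble
#'
#' Plain-text trajectory dialect: TSV with header
#' `frame chain resid name x y z`. Every frame must contain the same atoms
#' in the same order.
#'
#' @param path TSV file path.
#' @return An [ensemble()] with one model per frame.
#' @export
read_xyz_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("frame", "chain", "resid", "name", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("XYZ table must have columns: ", paste(need, collapse = ", "))
  frames <- unique(tab$frame)
  split_tab <- split(tab, factor(tab$frame, levels = frames))
  key <- function(d) paste(d$chain, d$resid, d$name, sep = "|")
  ref <- split_tab[[1]]
  for (m in seq_along(split_tab)) {
    if (nrow(split_tab[[m]]) != nrow(ref) ||
        !identical(key(split_tab[[m]]), key(ref)))
      stop(sprintf("inconsistent atom topology across models: model %d differs", m))
  }
  coords <- array(NA_real_, c(nrow(ref), 3L, length(split_tab)))
  for (m in seq_along(split_tab))
    coords[, , m] <- as.matrix(split_tab[[m]][, c("x", "y", "z")])
  atoms <- data.frame(
    serial = seq_len(nrow(ref)), name = ref$name, element = "C",
    resname = "ALA", resid = ref$resid, chain = ref$chain, altloc = "",
    occupancy = 1, type = "ATOM", stringsAsFactors = FALSE
  )
  ensemble(atoms, coords, model_ids = as.integer(seq_along(split_tab)))
}

#' Write an ensemble as a per-frame XYZ coordinate table
#' @param e ensemble.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_xyz_table <- function(e, path) {
  out <- do.call(rbind, lapply(seq_len(n_models(e)), function(m) {
    data.frame(frame = e$model_ids[m], chain = e$atoms$chain,
               resid = e$atoms$resid, name = e$atoms$name,
               x = e$coords[, 1, m], y = e$coords[, 2, m], z = e$coords[, 3, m])
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select atoms of an ensemble by attribute predicates
#'
#' All supplied predicates are combined with AND. Because every model shares
#' one topology, the returned indices are valid for every model and come in
#' deterministic file order.
#'
#' @param e ensemble.
#' @param chain,resname,name,element,altloc character vectors: keep atoms
#'   whose attribute is in the set (NULL = no constraint).
#' @param resid integer vector of residue numbers to keep.
#' @param entity `"protein"`, `"ligand"` or `"water"` (see
#'   [classify_entities()]).
#' @param water_resnames residue names recognised as water.
#' @return Integer atom indices (possibly empty).
#' @export
select_atoms <- function(e, chain = NULL, resid = NULL, resname = NULL,
                         name = NULL, element = NULL, altloc = NULL,
                         entity = NULL, water_resnames = c("HOH", "WAT")) {
  at <- e$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(name)) keep <- keep & at$name %in% name
  if (!is.null(element)) keep <- keep & at$element %in% element
  if (!is.null(altloc)) keep <- keep & at$altloc %in% altloc
  if (!is.null(entity)) {
    entity <- match.arg(entity, c("protein", "ligand", "water"))
    cls <- classify_entities(e, water_resnames = water_resnames, quiet = TRUE)
    keep <- keep & seq_len(nrow(at)) %in% cls[[entity]]
  }
  which(keep)
}

#' Partition the atoms of an ensemble into protein / ligand / water
#'
#' Protein: standard amino-acid residue names. Water: residue name in
#' `water_resnames`. Ligand: everything else (including modified residues
#' deposited as HETATM, which are flagged with a warning so they can be
#' reassigned). The three classes are disjoint and exhaustive.
#'
#' @param e ensemble.
#' @param water_resnames residue names recognised as water.
#' @param quiet suppress the modified-residue warning.
#' @return Named list of integer index vectors `protein`, `ligand`, `water`.
#' @export
classify_entities <- function(e, water_resnames = c("HOH", "WAT"),
                              quiet = FALSE) {
  rn <- e$atoms$resname
  water <- which(rn %in% water_resnames)
  protein <- which(rn %in% .standard_aa & !(seq_along(rn) %in% water))
  ligand <- setdiff(seq_along(rn), c(water, protein))
  if (!quiet) {
    mod <- unique(rn[ligand][rn[ligand] %in% .modified_aa])
    if (length(mod))
      warning("modified residue(s) classified as ligand: ",
              paste(mod, collapse = ", "))
  }
  list(protein = protein, ligand = ligand, water = water)
}

#' Reduce duplicated alternate locations to the highest-occupancy copy
#'
#' Within each `(chain, resid, name)` group carrying alternate-location
#' codes, keeps the altloc with the highest occupancy (first on ties).
#'
#' @param e ensemble.
#' @return Integer atom indices of the filtered topology.
#' @export
highest_occupancy_altloc <- function(e) {
  at <- e$atoms
  grp <- paste(at$chain, at$resid, at$name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[which.max(at$occupancy[idx])]
  }), use.names = FALSE)
  sort(keep)
}

#' Subset an ensemble to a set of atom indices
#' @param e ensemble.
#' @param idx integer atom indices.
#' @return A new [ensemble()] restricted to `idx` (file order preserved).
#' @export
subset_ensemble <- function(e, idx) {
  idx <- sort(unique(as.integer(idx)))
  ensemble(e$atoms[idx, , drop = FALSE],
           e$coords[idx, , , drop = FALSE],
           e$bfactor[idx, , drop = FALSE], e$model_ids)
}
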