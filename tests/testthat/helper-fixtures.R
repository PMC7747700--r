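# Small fixtures built in code at test time.

# hand-built ensemble: n_models x a tiny mixed topology (3 protein atoms,
# 1 ligand atom, 2 waters), coordinates supplied per model
toy_atoms <- function() {
  data.frame(
    serial = 1:6,
    name = c("CA", "CA", "SD", "O1", "O", "O"),
    element = c("C", "C", "S", "O", "O", "O"),
    resname = c("ALA", "MET", "MET", "LIG", "HOH", "HOH"),
    resid = c(1L, 2L, 2L, 10L, 101L, 102L),
    chain = c("A", "A", "A", "L", "W", "W"),
    altloc = "",
    occupancy = 1,
    type = c("ATOM", "ATOM", "ATOM", "HETATM", "HETATM", "HETATM"),
    stringsAsFactors = FALSE
  )
}

toy_ensemble <- function(n = 1, jitter = 0) {
  base <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(5, 1, 0),
                c(7, 1, 0), c(8, 3, 0), c(9, 5, 0))
  coords <- array(NA_real_, c(6, 3, n))
  for (m in seq_len(n)) coords[, , m] <- base + rnorm(18, sd = jitter)
  ensemble(toy_atoms(), coords, bfactor = matrix(50, 6, n))
}

# regular hexagon ring coordinates at a chosen centroid/normal
hex_ring <- function(ctr, nrm, radius = 1.39) {
  nrm <- nrm / sqrt(sum(nrm^2))
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  ang <- 2 * pi * (0:5) / 6
  t(sapply(ang, function(t0) ctr + radius * (cos(t0) * u + sin(t0) * v)))
}

# single-model ensemble holding just two rings (12 carbon atoms)
two_ring_model <- function(ctr1, nrm1, ctr2, nrm2) {
  atoms <- data.frame(
    serial = 1:12, name = paste0("C", 1:12), element = "C",
    resname = rep(c("RNG", "RNH"), each = 6),
    resid = rep(c(1L, 2L), each = 6), chain = "X", altloc = "",
    occupancy = 1, type = "HETATM", stringsAsFactors = FALSE
  )
  coords <- rbind(hex_ring(ctr1, nrm1), hex_ring(ctr2, nrm2))
  e <- ensemble(atoms, array(coords, c(12, 3, 1)))
  get_model(e, 1)
}

ring1_sel <- function() list(resname = "RNG")
ring2_sel <- function() list(resname = "RNH")

# write a multi-model PDB text fixture directly (bypasses the package
# writer so reader tests are independent of it)
write_fixture_pdb <- function(path, n_models = 3, n_atoms = 5) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(n_atoms)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        i, i, i * 3.8, m * 0.1, 0, 1.0, 20 + m))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
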