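# Independent oracles used by the geometry tests. These implementations are
# deliberately different algorithms from the ones in the package.

# Horn's quaternion method for optimal rigid superposition RMSD
quaternion_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  s <- t(a0) %*% b0
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(n4, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a0^2) + sum(b0^2) - 2 * lambda) / nrow(a)
  sqrt(max(msd, 0))
}

# exact buried area for two spheres (expanded by the probe): spherical caps
two_sphere_buried_exact <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (2 * pi * R1 * h1 + 2 * pi * R2 * h2) / 2
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# a tiny PDB file with two chains x three residues, one HETATM ligand
write_toy_pdb <- function(path) {
  lines <- c()
  serial <- 0
  emit <- function(record, name, resname, chain, resnum, x, y, z, el) {
    serial <<- serial + 1
    lines <<- c(lines, sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      record, serial, paste0(" ", name), resname, chain, resnum, x, y, z, el))
  }
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else 20
    for (rn in 1:3) {
      emit("ATOM", "N", "GLY", ch, rn, off + rn * 3, 0, 0, "N")
      emit("ATOM", "CA", "GLY", ch, rn, off + rn * 3 + 1.4, 0.5, 0, "C")
      emit("ATOM", "C", "GLY", ch, rn, off + rn * 3 + 2.2, 1.4, 0.3, "C")
      emit("ATOM", "O", "GLY", ch, rn, off + rn * 3 + 3.0, 1.8, 0.5, "O")
    }
  }
  emit("HETATM", "C1", "LIG", "L", 901, 50, 50, 50, "C")
  writeLines(c(lines, "END"), path)
  path
}

fixture_summaries <- function() build_reported_fixture()$summaries
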