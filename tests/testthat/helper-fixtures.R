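# shared fixture builders; everything is generated in code at test time

# minimal receptor-like topology with full side-chain atom sets for the
# salt-bridge selectors (Asp carboxylate pair, Arg guanidinium set)
make_sidechain_topology <- function() {
  atoms <- tibble::tibble(
    name    = c("CA", "OD1", "OD2",          # ASP 119 (3.49)
                "CA", "CE", "NE", "NH1", "NH2",  # ARG 120 (3.50)
                "CA", "CZ",                  # PHE 314 (6.44)
                "CA",                        # PRO 229 (5.50)
                "CA", "CD",                  # GLU 300 (6.30)
                "CA", "OH",                  # TYR 400 (7.53)
                "CA",                        # ALA 80 (2.40)
                "O"),                        # one water
    resname = c(rep("ASP", 3), rep("ARG", 5), rep("PHE", 2), "PRO",
                rep("GLU", 2), rep("TYR", 2), "ALA", "HOH"),
    resseq  = c(rep(119L, 3), rep(120L, 5), rep(314L, 2), 229L,
                rep(300L, 2), rep(400L, 2), 80L, 9000L),
    element = c("C", "O", "O", "C", "C", "N", "N", "N", "C", "C", "C",
                "C", "C", "C", "O", "C", "O"))
  bw <- microswitchr::bw_table(
    c("2.40", "3.49", "3.50", "5.50", "6.30", "6.44", "7.53"),
    c(80L, 119L, 120L, 229L, 300L, 314L, 400L),
    c("ALA", "ASP", "ARG", "PRO", "GLU", "PHE", "TYR"))
  xyz <- matrix(stats::rnorm(nrow(atoms) * 3, sd = 5), ncol = 3)
  microswitchr::topology_map(atoms, bw = bw, xyz = xyz)
}

# rigidly rotate points about a unit axis through their centroid (degrees);
# independent rotation construction for oracle checks
rotate_about <- function(x, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  r <- cos(th) * diag(3) + sin(th) * ux + (1 - cos(th)) * outer(u, u)
  cen <- colMeans(x)
  sweep(sweep(x, 2, cen) %*% t(r), 2, cen, `+`)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
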