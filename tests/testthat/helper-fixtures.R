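# shared fixtures built in code

# random rigid-body transform of a chromophore geometry
rigid_transform <- function(geom, seed = 1) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), sin(th[1]), 0,
                 -sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), sin(th[2]),
                 0, -sin(th[2]), cos(th[2])), 3)
  M <- Rx %*% Rz
  shift <- stats::runif(3, -10, 10)
  xyz <- as.matrix(geom[, c("x", "y", "z")]) %*% t(M)
  out <- geom
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}

# the published lambda_max values (nm) that serve as generator truths
printed_lambda_max <- c(515, 523, 525, 535, 542, 545, 550, 565, 569)

# planar reference geometry reused across tests
wt_geometry <- function() make_retinal_geometry(bla_target = 0.1160)
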