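## Independent 2x2 complex Jones-matrix oracle for retarder action.
## Conventions anchored to the physical worked example (a 10-degree
## retarder at 45 degrees drives a +40-degree elliptical state with
## azimuth 0 to right-circular): right-handed ellipticity is positive
## (S3 > 0), and the fast axis leads in phase.

jonesVector <- function(chiDeg, thetaDeg) {
  chi <- chiDeg * pi / 180
  th <- thetaDeg * pi / 180
  e0 <- c(cos(chi), 1i * sin(chi))
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot %*% e0
}

jonesRetarder <- function(deltaDeg, alphaDeg) {
  d <- deltaDeg * pi / 180
  a <- alphaDeg * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rot %*% diag(c(exp(1i * d / 2), exp(-1i * d / 2))) %*% t(rot)
}

stokesFromJones <- function(e) {
  ex <- e[1L]; ey <- e[2L]
  c(Mod(ex)^2 + Mod(ey)^2,
    Mod(ex)^2 - Mod(ey)^2,
    2 * Re(Conj(ex) * ey),
    2 * Im(Conj(ex) * ey))
}

## oracle: Stokes vector after a retarder, via Jones calculus
oracleRetarderStokes <- function(chiDeg, thetaDeg, deltaDeg, alphaDeg) {
  stokesFromJones(jonesRetarder(deltaDeg, alphaDeg) %*%
                    jonesVector(chiDeg, thetaDeg))
}

## smallest absolute angular difference on the 180-degree axial circle
axialDiff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

## smallest absolute hue difference on the 360-degree colour circle
hueDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
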