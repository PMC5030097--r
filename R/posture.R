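# Posture space: eigenworm computation, projection, reconstruction, phase.

#' Compute an eigenworm basis by PCA of tangent-angle profiles
#'
#' Eigendecomposes the 100 x 100 covariance matrix of an ensemble of
#' mean-subtracted tangent-angle profiles and returns the leading K
#' eigenvectors as an \code{\linkS4class{EigenwormBasis}}. Each eigenworm is
#' sign-fixed so that its largest-magnitude entry is positive (ties broken by
#' the first such entry), making the a3 > 0 = ventral-bend convention
#' reproducible.
#'
#' @param profiles numeric matrix, N x 100; each row a mean-subtracted
#'   tangent-angle profile (per-row mean 0).
#' @param K number of modes to keep (default 5).
#' @return an \code{EigenwormBasis} with K orthonormal vectors and the
#'   corresponding covariance eigenvalues.
#' @examples
#' set.seed(1)
#' u <- sin(2 * pi * (0:99) / 99); u <- u - mean(u)
#' prof <- outer(rnorm(50), u)
#' b <- computeEigenworms(prof, K = 1)
#' modeVariances(b)[1] / sum(modeVariances(b))  # 1: rank-1 ensemble
#' @export
computeEigenworms <- function(profiles, K = 5L) {
  profiles <- as.matrix(profiles)
  if (!all(is.finite(profiles))) stop("profiles must be finite")
  if (ncol(profiles) != 100L) stop("profiles must have 100 columns")
  if (nrow(profiles) < K)
    stop("need at least K = ", K, " profiles, got ", nrow(profiles))
  rm <- rowMeans(profiles)
  if (max(abs(rm)) > 1e-6)
    stop("profiles must be mean-subtracted (max |row mean| = ",
         format(max(abs(rm))), ")")
  C <- cov(profiles)
  e <- eigen(C, symmetric = TRUE)
  vec <- t(e$vectors[, seq_len(K), drop = FALSE])
  vec <- fixEigenSign(vec)
  new("EigenwormBasis", vectors = vec,
      variances = pmax(e$values[seq_len(K)], 0))
}

# flip rows so the largest-magnitude entry is positive; on magnitude ties the
# first tied entry decides
fixEigenSign <- function(vec) {
  for (i in seq_len(nrow(vec))) {
    j <- which.max(abs(vec[i, ]))
    if (vec[i, j] < 0) vec[i, ] <- -vec[i, ]
  }
  vec
}

#' Captured-variance fraction of an ensemble in a basis
#'
#' Fraction of total ensemble variance captured by the first \code{K} basis
#' vectors; the paper-style "cumulative variance" curve.
#'
#' @param basis an \code{EigenwormBasis}.
#' @param profiles optional N x 100 matrix of mean-subtracted profiles; if
#'   given, variances are measured on this ensemble rather than taken from
#'   the stored eigenvalues.
#' @param K number of leading modes (default: all).
#' @export
capturedVariance <- function(basis, profiles = NULL,
                             K = nrow(basisVectors(basis))) {
  if (is.null(profiles)) {
    v <- modeVariances(basis)
    return(sum(v[seq_len(K)]) / sum(v))
  }
  profiles <- as.matrix(profiles)
  ctr <- scale(profiles, center = TRUE, scale = FALSE)
  tot <- sum(ctr^2)
  proj <- ctr %*% t(basisVectors(basis)[seq_len(K), , drop = FALSE])
  sum(proj^2) / tot
}

#' Project a tangent-angle profile onto the eigenworm basis
#'
#' The overall orientation \eqn{\langle\theta\rangle} is the arithmetic mean
#' of the (head-to-tail unwrapped) angles; mode amplitudes are inner products
#' of the mean-subtracted angles with the eigenworms. Returns the
#' 6-component posture coordinate vector (a1..a5, theta).
#'
#' @param profile numeric(100) tangent angles, radians.
#' @param basis an \code{EigenwormBasis} with at least 5 vectors.
#' @return named numeric(6): a1..a5 and theta (the raw mean, not wrapped).
#' @export
projectPosture <- function(profile, basis) {
  checkProfile(profile)
  vec <- basisVectors(basis)
  if (nrow(vec) < 5L) stop("basis must contain at least 5 vectors")
  th <- unwrapAngles(profile)
  m <- mean(th)
  a <- drop(vec[1:5, , drop = FALSE] %*% (th - m))
  stats::setNames(c(a, m), c(paste0("a", 1:5), "theta"))
}

#' Reconstruct a tangent-angle profile from posture coordinates
#'
#' \eqn{\theta_F(s) = \langle\theta\rangle + \sum_{i=1}^5 a_i \hat e_i(s)}.
#' The result is not mean-subtracted; because eigenworms of mean-subtracted
#' ensembles are (numerically) mean-free, the mean of the reconstruction
#' equals the orientation.
#'
#' @param coords numeric(6): a1..a5, theta.
#' @inheritParams projectPosture
#' @return numeric(100) tangent angles.
#' @export
reconstructProfile <- function(coords, basis) {
  checkCoords(coords)
  vec <- basisVectors(basis)
  drop(coords[6] + coords[1:5] %*% vec[1:5, , drop = FALSE])
}

#' Body-wave phase angle
#'
#' \eqn{\varphi = -\mathrm{atan2}(a_2, a_1)}: the phase of the crawling body
#' wave in the (a1, a2) plane, defined so that \eqn{d\varphi/dt > 0} during
#' forward crawling. For a trajectory the per-frame phase is unwrapped along
#' time.
#'
#' @param x either a numeric(6) posture coordinate vector or a
#'   \code{\linkS4class{ModeTrajectory}}.
#' @return a single phase (radians) or an unwrapped per-frame phase vector.
#' @export
bodyPhase <- function(x) {
  if (is(x, "ModeTrajectory")) {
    m <- modeValues(x)
    if (nrow(m) < 2L)
      stop("phase trajectories need at least 2 frames")
    bad <- m[, 1] == 0 & m[, 2] == 0
    if (any(bad))
      stop("body-wave phase undefined: (a1, a2) = (0, 0) at frame ",
           which(bad)[1])
    return(unwrapAngles(-atan2(m[, 2], m[, 1])))
  }
  checkCoords(x)
  if (x[1] == 0 && x[2] == 0)
    stop("body-wave phase undefined for (a1, a2) = (0, 0)")
  -atan2(x[2], x[1])
}

#' Read / write an eigenworm basis file
#'
#' Plain-text CSV: a header line \code{# eigenworms K=<K>}, K rows of 100
#' values (the eigenworms), and one final row of K variances.
#'
#' @param path file path.
#' @export
writeEigenwormBasis <- function(basis, path) {
  vec <- basisVectors(basis)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eigenworms K=%d", nrow(vec)), con)
  utils::write.table(vec, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste(format(modeVariances(basis), digits = 17),
                   collapse = ","), con)
  invisible(path)
}

#' @rdname writeEigenwormBasis
#' @param basis an \code{EigenwormBasis} (for writing).
#' @export
readEigenwormBasis <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  K <- as.integer(sub("^# eigenworms K=", "", hdr))
  if (is.na(K)) stop("not a basis file: missing '# eigenworms K=' header")
  vec <- t(vapply(lines[1 + seq_len(K)],
                  function(l) as.numeric(strsplit(l, ",")[[1]]),
                  numeric(100)))
  dimnames(vec) <- NULL
  variances <- as.numeric(strsplit(lines[K + 2], ",")[[1]])
  new("EigenwormBasis", vectors = vec, variances = variances)
}

#' Export a mode trajectory as CSV
#'
#' Columns: frame, time_s, a1..a5, theta_mean, phase, and provenance when
#' available.
#'
#' @param traj a \code{ModeTrajectory}.
#' @param path file path.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname writeTrajectoryCSV
readTrajectoryCSV <- function(path) {
  df <- utils::read.csv(path)
  fr <- if (nrow(df) > 1) 1 / diff(df$time_s[1:2]) else 16
  prov <- if ("provenance" %in% names(df)) as.character(df$provenance)
          else character(0)
  newModeTrajectory(as.matrix(df[, paste0("a", 1:5)]), df$theta_mean,
                    round(fr, 6), prov)
}

#' @export
#' @method as.data.frame ModeTrajectory
as.data.frame.ModeTrajectory <- function(x, ...) {
  m <- modeValues(x)
  df <- data.frame(frame = seq_len(nrow(m)), time_s = frameTimes(x), m,
                   theta_mean = orientationValues(x),
                   phase = if (nrow(m) >= 2) bodyPhase(x) else NA_real_)
  if (length(x@provenance)) df$provenance <- x@provenance
  df
}

setMethod("as.data.frame", "ModeTrajectory", as.data.frame.ModeTrajectory)
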