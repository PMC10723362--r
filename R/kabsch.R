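# Rigid-body superposition (Kabsch) and TM-score with iterative
# refinement.  The TM-score is normalized by the *target* length, so
# swapping reference and target changes the score when lengths differ.

# optimal rotation/translation mapping points x onto y (rows = points)
kabsch_fit <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  H <- t(x0) %*% y0
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, translation = as.numeric(cy - cx %*% R))
}

apply_transform <- function(x, fit) {
  sweep(x %*% fit$rotation, 2, fit$translation, `+`)
}

tm_d0 <- function(L) max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)

#' TM-score of two structures under Kabsch superposition
#'
#' Least-squares rigid superposition of the corresponding residues,
#' then `TM = (1 / L_target) * sum_i 1 / (1 + (d_i / d0)^2)` with
#' `d0 = 1.24 (L_target - 15)^(1/3) - 1.8` (floored at 0.5 Angstrom)
#' and `L_target` the full residue count of the target structure.  The
#' superposition is refined iteratively on the residue pairs closer
#' than `d0`, until the score changes by less than `tol` (max 20
#' iterations); the best score seen is reported.
#'
#' @param ref,target `structure_model` objects.
#' @param correspondence 2-column integer matrix of (ref row, target
#'   row) residue pairs; default pairs residues positionally up to the
#'   shorter length.
#' @param tol convergence tolerance on the score.
#' @return a `tm_result`: `score`, `L_norm`, `rotation`,
#'   `translation` (mapping ref coordinates onto the target frame),
#'   `rmsd` (over all correspondence pairs), `n_pairs`.
#' @export
kabsch_tm <- function(ref, target, correspondence = NULL, tol = 1e-6) {
  if (is.null(correspondence)) {
    L <- min(nrow(ref), nrow(target))
    correspondence <- cbind(seq_len(L), seq_len(L))
  }
  wc_assert(nrow(correspondence) >= 3, "need >= 3 correspondence pairs",
            "wolclock_input_error")
  x <- structure_coords(ref)[correspondence[, 1], , drop = FALSE]
  y <- structure_coords(target)[correspondence[, 2], , drop = FALSE]
  Lt <- nrow(target)
  d0 <- tm_d0(Lt)
  score_of <- function(fit) {
    d <- sqrt(rowSums((apply_transform(x, fit) - y)^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / Lt, d = d)
  }
  fit <- kabsch_fit(x, y)
  if (!all(is.finite(fit$rotation)))
    wc_stop("degenerate point set: superposition failed",
            "wolclock_superposition_error")
  cur <- score_of(fit)
  best <- list(fit = fit, score = cur$score, d = cur$d)
  for (it in seq_len(20)) {
    keep <- cur$d < d0
    if (sum(keep) < 3) break
    fit2 <- kabsch_fit(x[keep, , drop = FALSE], y[keep, , drop = FALSE])
    nxt <- score_of(fit2)
    if (nxt$score > best$score)
      best <- list(fit = fit2, score = nxt$score, d = nxt$d)
    if (abs(nxt$score - cur$score) < tol) { cur <- nxt; break }
    cur <- nxt
  }
  structure(list(score = best$score, L_norm = Lt,
                 rotation = best$fit$rotation,
                 translation = best$fit$translation,
                 rmsd = sqrt(mean(best$d^2)),
                 n_pairs = nrow(correspondence)),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("TM-score %.4f (normalized to target length %d), rmsd %.3f A\n",
              x$score, x$L_norm, x$rmsd))
  invisible(x)
}
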