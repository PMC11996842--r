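#' Seeded random fixtures for property tests
#'
#' Deterministic generator of random Hilbert-space objects used throughout
#' the property-test suite: Hermitian operators, positive semidefinite
#' operators, unitaries (Haar via QR with phase fix), normalized states, and
#' CPTP channels (random isometry split into Kraus operators). A fixed
#' `seed` gives byte-identical output; the caller's RNG state is left
#' untouched.
#'
#' @param kind One of `"hermitian"`, `"psd"`, `"unitary"`, `"state"`,
#'   `"cptp"`.
#' @param dim Dimension, in `[2, 12]`.
#' @param seed Integer seed (optional; if `NULL` the current RNG stream is
#'   used).
#' @param scale Magnitude scale of the generated entries.
#' @param n_kraus Number of Kraus operators for `kind = "cptp"`.
#' @return A `qop`, `qstate`, or `kraus_instrument` matching `kind`.
#' @export
#' @examples
#' h <- generate_fixture("hermitian", dim = 3, seed = 1)
#' is_hermitian(h)
generate_fixture <- function(kind = c("hermitian", "psd", "unitary", "state", "cptp"),
                             dim = 3, seed = NULL, scale = 1, n_kraus = 2) {
  kind <- match.arg(kind)
  stopifnot(dim >= 2, dim <= 12)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  labels <- paste0("s", seq_len(dim))
  cnorm <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
  cmat <- function() matrix(cnorm(dim * dim), dim, dim) * scale
  switch(kind,
    hermitian = {
      b <- cmat()
      qop((b + Conj(t(b))) / 2, labels)
    },
    psd = {
      b <- cmat()
      qop(Conj(t(b)) %*% b / dim, labels)
    },
    unitary = {
      z <- matrix(cnorm(dim * dim), dim, dim)
      qr_z <- qr(z)
      q <- qr.Q(qr_z)
      r <- qr.R(qr_z)
      ph <- diag(r) / Mod(diag(r))
      qop(q %*% diag(ph, dim), labels)
    },
    state = {
      make_state(labels, cnorm(dim), normalize = TRUE)
    },
    cptp = {
      # random isometry V: C^dim -> C^(n_kraus*dim); rows split into Kraus ops
      z <- matrix(cnorm(n_kraus * dim * dim), n_kraus * dim, dim)
      qr_z <- qr(z)
      v <- qr.Q(qr_z)
      r <- qr.R(qr_z)
      ph <- diag(r) / Mod(diag(r))
      v <- v %*% diag(ph, dim)
      ops <- lapply(seq_len(n_kraus), function(k) {
        qop(v[((k - 1) * dim + 1):(k * dim), , drop = FALSE], labels)
      })
      kraus_instrument(ops)
    }
  )
}
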