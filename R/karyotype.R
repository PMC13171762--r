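#' Karyotype and feminization parameters
#'
#' The host has XX-female / X0-male sex determination; the two distinct X
#' chromosomes of the spider system are treated as one co-segregating linked
#' unit, so the composite states are `"XX"`, `"X0"` and `"OO"`. `OO` zygotes
#' (no X from either parent) are presumed inviable and never reproduce.
#'
#' @param state Character scalar, one of `"XX"`, `"X0"`, `"OO"`.
#' @return A validated karyotype string of class `karyotype`.
#' @export
karyotype <- function(state) {
  state <- match.arg(state, c("XX", "X0", "OO"))
  structure(state, class = "karyotype")
}

#' Feminization model parameters
#'
#' @param phi Probability in \[0,1\] that an infected X0 individual develops
#'   as a functional female; `1 - phi` is the feminization failure rate.
#' @param rho Relative egg number of X0 mothers versus XX mothers
#'   (dimensionless, default 1).
#' @param transmission Maternal transmission probability; the model assumes
#'   perfect vertical transmission, so this is fixed at 1.
#' @return A list of class `feminization_params`.
#' @export
feminization_params <- function(phi, rho = 1, transmission = 1) {
  stopifnot(is.numeric(phi), length(phi) == 1L, phi >= 0, phi <= 1)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0)
  if (!isTRUE(all.equal(transmission, 1))) {
    stop("maternal transmission is assumed perfect; transmission must be 1")
  }
  structure(list(phi = phi, rho = rho, transmission = 1),
            class = "feminization_params")
}

#' Gamete segregation distribution of a mother
#'
#' XX mothers transmit an X in every egg; X0 mothers segregate fairly, so
#' half their eggs carry no sex chromosome. OO individuals are inviable and
#' cannot produce gametes.
#'
#' @param parent A karyotype (string `"XX"` or `"X0"`, or a [karyotype()]).
#' @return Named numeric vector `c(X = , `0` = )` summing to 1.
#' @export
gamete_distribution <- function(parent) {
  state <- as.character(parent)
  switch(state,
    XX = c(X = 1.0, `0` = 0.0),
    X0 = c(X = 0.5, `0` = 0.5),
    OO = stop("OO is an inviable karyotype and cannot produce gametes"),
    stop("unknown karyotype: ", state)
  )
}

#' Offspring class distribution for a mated female
#'
#' Crosses the mother's gametes with those of an X0 male (all fathers are
#' X0 males; their infection status is irrelevant to karyotype outcomes).
#' Offspring infection equals the mother's (perfect maternal transmission).
#' X0 offspring of infected mothers are feminized with probability `phi`;
#' X0 offspring of uninfected mothers are male. OO offspring are inviable.
#'
#' @param mother Karyotype of the mother (`"XX"` or `"X0"`).
#' @param mother_infected Logical; must be `TRUE` for X0 mothers (an
#'   uninfected X0 individual is male and cannot be a mother).
#' @param params A [feminization_params()] object.
#' @return A data frame of class `offspring_distribution` with columns
#'   `karyotype`, `fate` (`"female"`, `"male"` or `"inviable"`), `infected`
#'   and `prob`; probabilities sum to 1.
#' @export
offspring_distribution <- function(mother, mother_infected, params) {
  state <- as.character(mother)
  if (!state %in% c("XX", "X0")) {
    stop("mother must be XX or X0 (OO individuals never reproduce)")
  }
  if (state == "X0" && !isTRUE(mother_infected)) {
    stop("an uninfected X0 individual develops as a male and cannot be a mother")
  }
  stopifnot(inherits(params, "feminization_params"))
  phi <- params$phi

  mg <- gamete_distribution(state)          # mother's gametes
  fg <- gamete_distribution("X0")           # father is always an X0 male

  # cross gametes -> zygote karyotype mass
  zyg <- c(XX = 0, X0 = 0, OO = 0)
  for (m in names(mg)) {
    for (f in names(fg)) {
      p <- mg[[m]] * fg[[f]]
      if (p == 0) next
      nx <- sum(c(m, f) == "X")
      k <- c("OO", "X0", "XX")[nx + 1L]
      zyg[[k]] <- zyg[[k]] + p
    }
  }

  inf <- isTRUE(mother_infected)
  rows <- list()
  add <- function(k, fate, p) {
    if (p > 0) rows[[length(rows) + 1L]] <<-
        data.frame(karyotype = k, fate = fate, infected = inf, prob = p)
  }
  add("XX", "female", zyg[["XX"]])
  if (inf) {
    add("X0", "female", zyg[["X0"]] * phi)
    add("X0", "male",   zyg[["X0"]] * (1 - phi))
  } else {
    add("X0", "male", zyg[["X0"]])
  }
  add("OO", "inviable", zyg[["OO"]])

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  class(out) <- c("offspring_distribution", class(out))
  out
}

#' Viability reduction implied by an offspring distribution
#'
#' Fraction of zygotes that are inviable (OO); 0.25 for an infected X0
#' mother under fair segregation.
#'
#' @param dist An [offspring_distribution()].
#' @return Numeric scalar in \[0,1\].
#' @export
inviable_fraction <- function(dist) {
  sum(dist$prob[dist$fate == "inviable"])
}
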