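#' Define a polyprotic acid (or its salt) for the equilibrium solver
#'
#' @param name species name.
#' @param conc total (analytical) concentration in the mixture, mol/L.
#' @param pka ascending vector of dissociation constants (pKa scale).
#' @param charge_protonated charge of the fully protonated form (0 for
#'   citric and phosphoric acid).
#' @param counterion_charge total counterion charge contributed per
#'   formula unit as dissolved (e.g. +2 for disodium hydrogen phosphate's
#'   two sodium ions; 0 for the free acid).
#' @return An object of class `acid_species`.
#' @export
acid_species <- function(name, conc, pka, charge_protonated = 0,
                         counterion_charge = 0) {
  stopifnot(conc >= 0, length(pka) >= 1, all(diff(pka) > 0))
  structure(list(name = name, conc = conc, pka = as.numeric(pka),
                 charge_protonated = charge_protonated,
                 counterion_charge = counterion_charge),
            class = "acid_species")
}

#' A volumetric citrate-phosphate buffer mixture
#'
#' The universal calibration buffer is mixed from two stocks: disodium
#' hydrogen phosphate (default 0.2 M) and citric acid monohydrate
#' (default 0.1 M); varying their volume ratio tunes the pH over roughly
#' 2.5-8.
#'
#' @param phosphate_ml,citrate_ml volumes of the two stocks, ml.
#' @param phosphate_M,citrate_M stock concentrations, mol/L.
#' @param temperature degrees C (only 25 is modelled; retained as
#'   provenance).
#' @param activity logical; apply the Davies activity correction when
#'   solving for pH.
#' @return An object of class `buffer_mixture`.
#' @export
buffer_mixture <- function(phosphate_ml, citrate_ml,
                           phosphate_M = 0.2, citrate_M = 0.1,
                           temperature = 25, activity = FALSE) {
  stopifnot(phosphate_ml >= 0, citrate_ml >= 0,
            phosphate_ml + citrate_ml > 0)
  total <- phosphate_ml + citrate_ml
  species <- list(
    acid_species("phosphoric acid (as Na2HPO4)",
                 conc = phosphate_M * phosphate_ml / total,
                 pka = buffer_constants$pka_phosphoric,
                 counterion_charge = 2),
    acid_species("citric acid",
                 conc = citrate_M * citrate_ml / total,
                 pka = buffer_constants$pka_citric))
  structure(list(phosphate_ml = phosphate_ml, citrate_ml = citrate_ml,
                 phosphate_M = phosphate_M, citrate_M = citrate_M,
                 total_ml = total, species = species,
                 temperature = temperature, activity = activity),
            class = "buffer_mixture")
}

# Fraction of each deprotonation state (0..n protons removed) at [H+] = h,
# using concentration-scale constants ka (length n). Returns matrix states x 1.
speciation_fractions <- function(h, ka) {
  n <- length(ka)
  # unnormalized term for j protons removed: h^(n-j) * prod(ka[1:j])
  terms <- vapply(0:n, function(j) h^(n - j) * prod(ka[seq_len(j)]), numeric(1))
  terms / sum(terms)
}

# Signed charge-balance residual (eq/L) at [H+] = h for a list of species,
# with concentration-scale constants supplied per species.
charge_balance <- function(h, species, ka_list, kw_c) {
  res <- h - kw_c / h
  for (i in seq_along(species)) {
    sp <- species[[i]]
    if (sp$conc == 0) next
    alpha <- speciation_fractions(h, ka_list[[i]])
    j <- 0:length(sp$pka)
    res <- res + sp$conc * sum(alpha * (sp$charge_protonated - j)) +
      sp$conc * sp$counterion_charge
  }
  res
}

davies_gamma <- function(z, I) {
  if (I <= 0) return(rep(1, length(z)))
  sqI <- sqrt(I)
  10^(-buffer_constants$davies_A * z^2 * (sqI / (1 + sqI) - 0.3 * I))
}

#' Solve a buffer mixture for its equilibrium pH
#'
#' Finds the root of the charge-balance equation (protons, hydroxide, all
#' acid speciation states and counterions) by bisection on pH in [0, 14].
#' With `activity = TRUE` (on the mixture) the Davies equation corrects
#' the equilibrium constants for ionic strength, iterating speciation and
#' ionic strength to convergence; the returned pH is then the proton
#' activity, which is what a glass electrode reads.
#'
#' @param mix a [buffer_mixture()].
#' @return The equilibrium pH (scalar).
#' @export
solve_ph <- function(mix) {
  stopifnot(inherits(mix, "buffer_mixture"))
  species <- mix$species
  ka_thermo <- lapply(species, function(sp) 10^(-sp$pka))
  kw <- buffer_constants$kw

  solve_conc <- function(ka_list, kw_c) {
    f <- function(ph) charge_balance(10^(-ph), species, ka_list, kw_c)
    lo <- 0; hi <- 14
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi))
      stop("charge balance has no sign change on pH [0, 14]; check species definitions")
    for (it in 1:100) {
      mid <- (lo + hi) / 2; fm <- f(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }

  if (!isTRUE(mix$activity))
    return(solve_conc(ka_thermo, kw))

  # Davies iteration: conditional constants at the current ionic strength
  I <- 0; ph_conc <- solve_conc(ka_thermo, kw)
  for (iter in 1:100) {
    gH <- davies_gamma(1, I)
    ka_cond <- lapply(species, function(sp) {
      z0 <- sp$charge_protonated
      n <- length(sp$pka)
      # step j: H_{n-j+1}A^{z0-j+1} <-> H+ + H_{n-j}A^{z0-j}
      vapply(seq_len(n), function(j)
        10^(-sp$pka[j]) * davies_gamma(z0 - j + 1, I) /
          (gH * davies_gamma(z0 - j, I)), numeric(1))
    })
    kw_c <- kw / (gH * davies_gamma(-1, I))
    ph_new <- solve_conc(ka_cond, kw_c)
    h <- 10^(-ph_new)
    # ionic strength from full speciation
    I_new <- 0.5 * (h * 1^2 + (kw_c / h) * 1^2)
    for (i in seq_along(species)) {
      sp <- species[[i]]
      if (sp$conc == 0) next
      alpha <- speciation_fractions(h, ka_cond[[i]])
      j <- 0:length(sp$pka)
      I_new <- I_new + 0.5 * sp$conc *
        (sum(alpha * (sp$charge_protonated - j)^2) + abs(sp$counterion_charge))
    }
    converged <- abs(ph_new - ph_conc) < 1e-6 && abs(I_new - I) < 1e-8
    ph_conc <- ph_new; I <- I_new
    if (converged) break
  }
  # activity pH (what the meter reads)
  -log10(10^(-ph_conc) * davies_gamma(1, I))
}

#' Design a citrate-phosphate recipe for a target pH
#'
#' Finds the phosphate volume fraction whose solved pH matches the target
#' (the solved pH is strictly increasing in the phosphate fraction, so a
#' 1-D monotone root find suffices) and scales to the requested total
#' volume.
#'
#' @param target_ph target pH.
#' @param total_ml total buffer volume, ml (default 20).
#' @param activity apply the Davies correction (default `TRUE`, matching
#'   bench conditions at ~0.1 M ionic strength).
#' @param tol root-finding tolerance in pH units.
#' @inheritParams buffer_mixture
#' @return An object of class `buffer_recipe`: target pH, solved volumes,
#'   achieved model pH, and residual.
#' @export
design_recipe <- function(target_ph, total_ml = 20, phosphate_M = 0.2,
                          citrate_M = 0.1, activity = TRUE, tol = 1e-4) {
  ph_at <- function(x) {  # x = phosphate volume fraction
    solve_ph(buffer_mixture(x * total_ml, (1 - x) * total_ml,
                            phosphate_M, citrate_M, activity = activity))
  }
  lo <- ph_at(0); hi <- ph_at(1)
  if (target_ph < lo || target_ph > hi)
    stop(sprintf("target pH %.2f outside achievable span [%.2f, %.2f]",
                 target_ph, lo, hi))
  root <- stats::uniroot(function(x) ph_at(x) - target_ph,
                         interval = c(0, 1), tol = 1e-9)
  x <- root$root
  achieved <- ph_at(x)
  if (abs(achieved - target_ph) > tol)
    warning(sprintf("design residual %.2g pH exceeds tol", achieved - target_ph))
  structure(list(target_ph = target_ph,
                 phosphate_ml = x * total_ml,
                 citrate_ml = (1 - x) * total_ml,
                 achieved_ph = achieved,
                 residual = achieved - target_ph,
                 activity = activity),
            class = "buffer_recipe")
}

#' @export
print.buffer_recipe <- function(x, ...) {
  cat(sprintf("buffer_recipe: pH %.2f <- %.2f ml phosphate + %.2f ml citrate (model pH %.3f)\n",
              x$target_ph, x$phosphate_ml, x$citrate_ml, x$achieved_ph))
  invisible(x)
}

#' Tabulate designed recipes for the standard calibration series
#'
#' @param ph_values target pH values (default the twelve-buffer series
#'   2.5-8.0).
#' @param total_ml total volume per buffer.
#' @param activity apply the Davies correction.
#' @return A data.frame with columns `ph`, `phosphate_ml`, `citrate_ml`,
#'   `achieved_ph`.
#' @export
design_buffer_table <- function(ph_values = buffer_series_recipes$ph,
                                total_ml = 20, activity = TRUE) {
  rows <- lapply(ph_values, function(p) {
    r <- design_recipe(p, total_ml = total_ml, activity = activity)
    data.frame(ph = p, phosphate_ml = r$phosphate_ml,
               citrate_ml = r$citrate_ml, achieved_ph = r$achieved_ph)
  })
  do.call(rbind, rows)
}

#' Mass of solute needed for a stock solution
#'
#' @param concentration mol/L.
#' @param volume_l litres.
#' @param molar_mass g/mol.
#' @return Mass in grams, rounded to 3 decimal places (weighing precision).
#' @examples
#' stock_mass(0.2, 0.25, 141.96)   # 7.098 g disodium hydrogen phosphate
#' stock_mass(0.1, 0.25, 210.14)   # 5.254 g citric acid monohydrate
#' @export
stock_mass <- function(concentration, volume_l, molar_mass) {
  stopifnot(concentration >= 0, volume_l >= 0, molar_mass >= 0)
  round(concentration * volume_l * molar_mass, 3)
}

#' Concentration after dilution
#'
#' @param c_stock stock concentration (any unit).
#' @param v_stock volume of stock taken.
#' @param v_total final total volume (same unit as `v_stock`).
#' @return Diluted concentration `c_stock * v_stock / v_total`.
#' @examples
#' dilution(10, 5, 50)  # 10 mg/ml nanosensors, 5 ul into 50 ul -> 1 mg/ml
#' @export
dilution <- function(c_stock, v_stock, v_total) {
  stopifnot(v_stock > 0)
  if (v_total < v_stock)
    stop("total volume must be at least the stock volume")
  c_stock * v_stock / v_total
}
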