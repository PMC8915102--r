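#' Configuration for the synthetic prostate phantom cohort
#'
#' Defines the class-conditional structure of generated cases: mono-exponential
#' diffusion signal decay with a lower apparent diffusion coefficient (ADC) in
#' malignant cases, T2-weighted textural heterogeneity controlled by a spatial
#' correlation length (shorter in malignant cases), lesion surface complexity
#' controlled by the amplitude of an angular radial perturbation (larger in
#' malignant cases), and a log-normal PSA distribution truncated below at
#' 4 ng/mL (the clinical inclusion criterion), with a higher malignant mean.
#'
#' @param n_cases number of cases to generate.
#' @param class_balance fraction of malignant cases in `[0, 1]`.
#' @param grid_shape integer vector of three voxel dimensions.
#' @param b_values diffusion b-values in s/mm^2; must start at 0.
#' @param adc_benign_mean,adc_malignant_mean class mean ADC in mm^2/s;
#'   malignant must be lower than benign.
#' @param adc_sd between-case ADC standard deviation, mm^2/s.
#' @param noise_sd additive Gaussian noise on DW signals (signal units);
#'   noisy signals are clipped at a floor of 1 so the ADC logarithm stays
#'   defined.
#' @param texture_corr_len_benign,texture_corr_len_malignant correlation
#'   length (voxels) of the smoothed random field behind the T2W texture.
#' @param lesion_spike_amp_benign,lesion_spike_amp_malignant unitless
#'   amplitude of the angular perturbation of the lesion surface radius.
#' @param lesion_radius mean lesion radius in voxels.
#' @param psa_benign_mean,psa_malignant_mean class mean PSA in ng/mL (> 4).
#' @param psa_sdlog log-scale SD of the PSA log-normal.
#' @param s0 baseline (b = 0) signal level inside the prostate.
#' @param seed random-generator seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_cases = 80,
                           class_balance = 37 / 80,
                           grid_shape = c(28L, 28L, 20L),
                           b_values = c(0, 100, 200, 300, 400, 500, 600, 700, 1400),
                           adc_benign_mean = 1.8e-3,
                           adc_malignant_mean = 0.9e-3,
                           adc_sd = 0.15e-3,
                           noise_sd = 10,
                           texture_corr_len_benign = 3,
                           texture_corr_len_malignant = 1.2,
                           lesion_spike_amp_benign = 0.08,
                           lesion_spike_amp_malignant = 0.35,
                           lesion_radius = 4.5,
                           psa_benign_mean = 8,
                           psa_malignant_mean = 20,
                           psa_sdlog = 0.35,
                           s0 = 1000,
                           seed = 1L) {
  stopifnot(n_cases >= 0, class_balance >= 0, class_balance <= 1,
            length(grid_shape) == 3, all(grid_shape >= 4),
            length(b_values) >= 2, all(b_values >= 0),
            adc_sd >= 0, noise_sd >= 0, lesion_radius > 0,
            psa_benign_mean > 4, psa_malignant_mean > 4)
  if (b_values[1] != 0)
    stop("first b-value must be 0 (the baseline acquisition)")
  if (adc_malignant_mean >= adc_benign_mean)
    stop("adc_malignant_mean must be below adc_benign_mean: ",
         "malignant tissue restricts water diffusion")
  structure(list(
    n_cases = as.integer(n_cases), class_balance = class_balance,
    grid_shape = as.integer(grid_shape), b_values = b_values,
    adc_benign_mean = adc_benign_mean, adc_malignant_mean = adc_malignant_mean,
    adc_sd = adc_sd, noise_sd = noise_sd,
    texture_corr_len_benign = texture_corr_len_benign,
    texture_corr_len_malignant = texture_corr_len_malignant,
    lesion_spike_amp_benign = lesion_spike_amp_benign,
    lesion_spike_amp_malignant = lesion_spike_amp_malignant,
    lesion_radius = lesion_radius,
    psa_benign_mean = psa_benign_mean, psa_malignant_mean = psa_malignant_mean,
    psa_sdlog = psa_sdlog, s0 = s0, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Generate a labeled synthetic cohort
#'
#' Produces one `prostate_case` per subject. The prostate is an ellipsoid
#' centred in the grid; the lesion is a star-shaped solid inside it whose
#' surface radius is `r0 * (1 + a * P(theta, phi))` with `P` a band-limited
#' random angular field and `a` the class-dependent spike amplitude. DW
#' signals follow `s_n = s0 * exp(-b_n * D)` plus Gaussian noise clipped at a
#' floor of 1; `D` is drawn per case from the class ADC distribution. The T2W
#' volume is a Gaussian random field smoothed at the class correlation length.
#'
#' @param config a [phantom_config()].
#' @return a list of `prostate_case` objects, each with elements
#'   `case_id`, `dw_volumes` (named by b-value), `t2w_volume`,
#'   `prostate_mask`, `lesion_mask`, `psa`, `label`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  n <- config$n_cases
  if (n == 0) return(list())
  n_mal <- round(config$class_balance * n)
  labels <- c(rep("malignant", n_mal), rep("benign", n - n_mal))
  case_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    generate_case(sprintf("case_%03d", i), labels[i], case_seeds[i], config)
  })
}

# One phantom case. Deterministic given (label, seed, config).
generate_case <- function(case_id, label, seed, config) {
  set.seed(seed)
  d <- config$grid_shape
  mal <- label == "malignant"

  centre <- (d + 1) / 2
  semi <- d / 2 - 1.5                      # prostate ellipsoid semi-axes
  gx <- slice.index(array(0, d), 1) - centre[1]
  gy <- slice.index(array(0, d), 2) - centre[2]
  gz <- slice.index(array(0, d), 3) - centre[3]
  prostate <- (gx / semi[1])^2 + (gy / semi[2])^2 + (gz / semi[3])^2 <= 1

  # Star-shaped lesion: smooth base radius plus band-limited angular bumps.
  amp <- if (mal) config$lesion_spike_amp_malignant else config$lesion_spike_amp_benign
  r0 <- config$lesion_radius
  lx <- gx; ly <- gy; lz <- gz                       # lesion centred with prostate
  rr <- sqrt(lx^2 + ly^2 + lz^2)
  theta <- acos(ifelse(rr > 0, pmin(pmax(lz / pmax(rr, 1e-12), -1), 1), 1))
  phi <- atan2(ly, lx) %% (2 * pi)
  P <- angular_perturbation_field(theta, phi, degrees = 2:6)
  r_surf <- r0 * (1 + amp * P)
  lesion <- rr <= r_surf
  if (any(lesion & !prostate))
    stop("lesion does not fit inside the prostate mask; ",
         "reduce lesion_radius or spike amplitude")

  # DW series: per-case ADC from the class distribution, truncated positive.
  mu <- if (mal) config$adc_malignant_mean else config$adc_benign_mean
  D <- -1
  while (D <= 0) D <- rnorm(1, mu, config$adc_sd)
  dw <- lapply(config$b_values, function(b) {
    sig <- array(20, d)                              # air-ish background
    sig[prostate] <- config$s0 * exp(-b * D)
    if (config$noise_sd > 0)
      sig <- sig + array(rnorm(prod(d), 0, config$noise_sd), d)
    pmax(sig, 1)                                     # positivity floor
  })
  names(dw) <- as.character(config$b_values)

  # T2W: white noise smoothed at the class correlation length, rescaled.
  cl <- if (mal) config$texture_corr_len_malignant else config$texture_corr_len_benign
  field <- gauss_smooth3d(array(rnorm(prod(d)), d), cl)
  field <- field / max(sd(field[prostate]), 1e-12)
  t2w <- array(50, d)
  t2w[prostate] <- 500 + 150 * field[prostate]

  psa_mu <- if (mal) config$psa_malignant_mean else config$psa_benign_mean
  psa <- 0
  while (psa <= 4)
    psa <- rlnorm(1, log(psa_mu) - config$psa_sdlog^2 / 2, config$psa_sdlog)

  structure(list(
    case_id = case_id, dw_volumes = dw, t2w_volume = t2w,
    prostate_mask = prostate, lesion_mask = lesion,
    psa = psa, label = label
  ), class = "prostate_case")
}

# Band-limited random angular field, unit-normalised to max |P| = 1.
# Evaluated with the package's real spherical-harmonics basis.
angular_perturbation_field <- function(theta, phi, degrees) {
  out <- array(0, dim(theta))
  th <- as.vector(theta); ph <- as.vector(phi)
  for (l in degrees) {
    w <- rnorm(2 * l + 1)
    out <- out + array(sh_basis_block(l, th, ph) %*% w, dim(theta))
  }
  out / max(abs(out))
}

#' @export
print.prostate_case <- function(x, ...) {
  cat("<prostate_case>", x$case_id, "-", x$label,
      sprintf("| PSA %.1f ng/mL | grid %s | %d DW b-values\n",
              x$psa, paste(dim(x$t2w_volume), collapse = "x"),
              length(x$dw_volumes)))
  invisible(x)
}

#' Write a cohort to NIfTI volumes plus a CSV manifest
#'
#' @param cases list of `prostate_case` objects.
#' @param out_dir writable output directory (created if absent).
#' @return path of the written manifest CSV, invisibly readable back with
#'   [read_cohort()].
#' @export
write_cohort <- function(cases, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cases, `[[`, "", "case_id")
  if (anyDuplicated(ids)) stop("duplicate case_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(cases, function(cs) {
    paths <- c()
    for (b in names(cs$dw_volumes)) {
      p <- file.path(out_dir, sprintf("%s_dwi_b%s.nii.gz", cs$case_id, b))
      RNifti::writeNifti(cs$dw_volumes[[b]], p)
      paths[paste0("dwi_b", b)] <- basename(p)
    }
    p <- file.path(out_dir, paste0(cs$case_id, "_t2w.nii.gz"))
    RNifti::writeNifti(cs$t2w_volume, p); paths["t2w"] <- basename(p)
    p <- file.path(out_dir, paste0(cs$case_id, "_prostate_mask.nii.gz"))
    RNifti::writeNifti(cs$prostate_mask + 0, p); paths["prostate_mask"] <- basename(p)
    p <- file.path(out_dir, paste0(cs$case_id, "_lesion_mask.nii.gz"))
    RNifti::writeNifti(cs$lesion_mask + 0, p); paths["lesion_mask"] <- basename(p)
    c(case_id = cs$case_id, label = cs$label, psa = format(cs$psa, digits = 15),
      paths)
  })
  manifest <- file.path(out_dir, "manifest.csv")
  if (length(rows)) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(case_id = character(), label = character(),
                     psa = character())
  }
  utils::write.csv(df, manifest, row.names = FALSE)
  manifest
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest path to the manifest CSV.
#' @return list of `prostate_case` objects.
#' @export
read_cohort <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                        colClasses = "character")
  dir <- dirname(manifest)
  vol <- function(p) {
    v <- RNifti::readNifti(file.path(dir, p))
    array(as.numeric(v), dim(v))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    bcols <- grep("^dwi_b", names(df), value = TRUE)
    dw <- lapply(bcols, function(cn) vol(row[[cn]]))
    names(dw) <- sub("^dwi_b", "", bcols)
    structure(list(
      case_id = row$case_id,
      dw_volumes = dw,
      t2w_volume = vol(row$t2w),
      prostate_mask = vol(row$prostate_mask) > 0.5,
      lesion_mask = vol(row$lesion_mask) > 0.5,
      psa = as.numeric(row$psa),
      label = row$label
    ), class = "prostate_case")
  })
}
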