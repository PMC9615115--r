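#' Spectrum container
#' @noRd
new_spectrum <- function(grid, chi, tensor_element, subset_name,
                         n_frames, mean_subset_size, per_water = FALSE) {
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("frequency grid must be strictly increasing")
  stopifnot(all(is.finite(Re(chi))), all(is.finite(Im(chi))))
  structure(list(frequency_grid = grid, chi_values = chi,
                 tensor_element = tensor_element, subset_name = subset_name,
                 n_frames = n_frames, mean_subset_size = mean_subset_size,
                 per_water = per_water),
            class = "sfg_spectrum")
}

#' @export
print.sfg_spectrum <- function(x, ...) {
  cat(sprintf(
    "sfg_spectrum [%s] subset '%s': %d points, %s frames, mean size %.2f%s\n",
    x$tensor_element, x$subset_name, length(x$frequency_grid),
    as.character(x$n_frames), x$mean_subset_size,
    if (isTRUE(x$per_water)) " (per water)" else ""))
  invisible(x)
}

#' Water subset over a trajectory
#'
#' @param name subset name.
#' @param members list (one element per frame) of water molecule ids.
#' @param topology optional topology to validate ids against.
#' @return an `sfg_subset`.
#' @export
sfg_subset <- function(name, members, topology = NULL) {
  members <- lapply(members, function(m) sort(unique(as.integer(m))))
  if (!is.null(topology)) {
    wm <- water_molecules(topology)
    bad <- setdiff(unique(unlist(members)), wm)
    if (length(bad))
      stop("subset '", name, "' references non-water molecules: ",
           paste(head(bad), collapse = ", "))
  }
  structure(list(name = name, members = members), class = "sfg_subset")
}

.element_idx <- function(element) {
  # lab axes x=1, y=2, z=3; element "ijk" = (SFG, visible, IR) indices
  element <- match.arg(element, c("zyx", "yyz"))
  match(strsplit(element, "")[[1]], c("x", "y", "z"))
}

#' Stick spectrum of one frame for a water subset
#'
#' Maps each subset water's two O-H bonds to chromophores, forms the
#' intramolecular exciton pair, and returns one stick per eigenmode with
#' weight alpha_ij * mu_k for the requested tensor element (i,j,k) =
#' (SFG, visible, IR) lab indices.
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology`.
#' @param subset_members water molecule ids in this frame (may be empty).
#' @param element "zyx" (chiral) or "yyz" (achiral).
#' @param coeffs a `map_coefficients`.
#' @return data frame with columns `omega`, `weight`, `molecule_id`,
#'   `mode`; zero rows for an empty subset.
#' @export
frame_sticks <- function(frame, topology, subset_members,
                         element = c("zyx", "yyz"),
                         coeffs = load_map_coefficients()) {
  idx <- .element_idx(element)
  if (!length(subset_members))
    return(data.frame(omega = numeric(0), weight = numeric(0),
                      molecule_id = integer(0), mode = integer(0)))
  chs <- build_chromophores(frame, topology, coeffs,
                            molecules = subset_members)
  mol <- vapply(chs, `[[`, 1, "molecule_id")
  out <- lapply(unique(mol), function(m) {
    pair <- chs[mol == m]
    ex <- build_exciton_pair(pair[[1]], pair[[2]], coeffs)
    w <- vapply(1:2, function(k)
      ex$alpha[[k]][idx[1], idx[2]] * ex$mu[k, idx[3]], numeric(1))
    data.frame(omega = ex$omega, weight = w, molecule_id = m, mode = 1:2)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Complex line shape centered at omega0, evaluated on a grid
#'
#' The imaginary part is the normalized Lorentzian or Gaussian; the real
#' part is its Kramers-Kronig partner, so the pair behaves like the
#' complex susceptibility of a resonance at omega0.
#' @noRd
lineshape_complex <- function(grid, omega0, width,
                              lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  delta <- omega0 - grid
  if (lineshape == "lorentzian") {
    (1 / pi) / complex(real = delta, imaginary = -width)
  } else {
    x <- delta / (sqrt(2) * width)
    (1 / (width * sqrt(2 * pi))) *
      complex(real = (2 / sqrt(pi)) * dawson_fn(x), imaginary = exp(-x^2))
  }
}

dawson_fn <- function(x) {
  # Dawson integral F(x); series via erfi for small x, asymptotic beyond
  out <- numeric(length(x))  # F(0) = 0; erfz chokes on exactly 0
  small <- abs(x) < 5 & x != 0
  large <- abs(x) >= 5
  if (any(small)) {
    xs <- x[small]
    erfi <- Re(-1i * pracma::erfz(complex(imaginary = xs)))
    out[small] <- sqrt(pi) / 2 * exp(-xs^2) * erfi
  }
  if (any(large)) {
    xl <- x[large]
    out[large] <- 1 / (2 * xl) + 1 / (4 * xl^3) + 3 / (8 * xl^5)
  }
  out
}

#' Accumulate a chi(2) spectrum over frames
#'
#' Inhomogeneous-limit spectrum: each frame contributes broadened sticks
#' and the result is the frame average,
#' chi(w) = (1/n_frames) sum_frames sum_sticks weight * L(w - w_stick).
#' The imaginary part is the reported observable (phase-resolved
#' convention); the real part is retained.
#'
#' @param frames list of `sfg_frame`s.
#' @param topology an `sfg_topology`.
#' @param subset an `sfg_subset` whose `members` list matches `frames`
#'   in length (or length 1, recycled).
#' @param element "zyx" or "yyz".
#' @param grid frequency grid, cm-1 (strictly increasing).
#' @param lineshape "lorentzian" (default) or "gaussian".
#' @param width half-width (Lorentzian) or sigma (Gaussian), cm-1.
#' @param coeffs a `map_coefficients`.
#' @return an `sfg_spectrum`.
#' @export
accumulate_spectrum <- function(frames, topology, subset,
                                element = c("zyx", "yyz"),
                                grid = seq(2800, 4000, by = 1),
                                lineshape = c("lorentzian", "gaussian"),
                                width = 5,
                                coeffs = load_map_coefficients()) {
  element <- match.arg(element)
  lineshape <- match.arg(lineshape)
  stopifnot(width > 0)
  if (!length(frames)) stop("zero frames: nothing to accumulate")
  members <- subset$members
  if (length(members) == 1L) members <- rep(members, length(frames))
  stopifnot(length(members) == length(frames))
  chi <- complex(length(grid))
  sizes <- numeric(length(frames))
  for (f in seq_along(frames)) {
    sizes[f] <- length(members[[f]])
    st <- frame_sticks(frames[[f]], topology, members[[f]], element, coeffs)
    for (i in seq_len(nrow(st)))
      chi <- chi + st$weight[i] *
        lineshape_complex(grid, st$omega[i], width, lineshape)
  }
  chi <- chi / length(frames)
  new_spectrum(grid, chi, element, subset$name, length(frames), mean(sizes))
}

#' Normalize a spectrum per water molecule
#'
#' Divides chi by the mean subset size over the accumulated frames,
#' giving the signal per water molecule of the subset.
#'
#' @param result an `sfg_spectrum`.
#' @return the normalized `sfg_spectrum` (flagged `per_water`).
#' @export
normalize_per_water <- function(result) {
  stopifnot(inherits(result, "sfg_spectrum"))
  if (!is.finite(result$mean_subset_size) || result$mean_subset_size <= 0)
    stop("cannot normalize: empty subset")
  new_spectrum(result$frequency_grid,
               result$chi_values / result$mean_subset_size,
               result$tensor_element, result$subset_name, result$n_frames,
               result$mean_subset_size, per_water = TRUE)
}

#' Band area of the imaginary spectrum
#'
#' Trapezoidal integral of Im chi (signed) or |Im chi| (absolute) over
#' [lo, hi]; band edges are linearly interpolated onto the grid.
#'
#' @param result an `sfg_spectrum`.
#' @param lo,hi integration limits (cm-1), inside the grid.
#' @param mode "signed" or "absolute".
#' @return scalar area.
#' @export
band_area <- function(result, lo, hi, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  g <- result$frequency_grid
  if (lo >= hi) stop("lo must be < hi")
  if (lo < min(g) || hi > max(g)) stop("band outside the frequency grid")
  y <- Im(result$chi_values)
  if (mode == "absolute") y <- abs(y)
  inside <- g > lo & g < hi
  xs <- c(lo, g[inside], hi)
  ys <- c(approx(g, y, lo)$y, y[inside], approx(g, y, hi)$y)
  pracma::trapz(xs, ys)
}

#' Two-band significance test on the imaginary spectrum
#'
#' Two-sided two-sample t-test comparing Im chi sampled at grid points
#' inside a signal band against a baseline band.
#'
#' @param result an `sfg_spectrum`.
#' @param signal_band,baseline_band length-2 ranges (cm-1), inside the
#'   grid and non-overlapping.
#' @return the p-value.
#' @export
region_significance <- function(result, signal_band, baseline_band) {
  g <- result$frequency_grid
  for (b in list(signal_band, baseline_band))
    if (b[1] < min(g) || b[2] > max(g)) stop("band outside the frequency grid")
  if (signal_band[2] > baseline_band[1] && baseline_band[2] > signal_band[1])
    stop("bands overlap")
  x <- Im(result$chi_values)[g >= signal_band[1] & g <= signal_band[2]]
  y <- Im(result$chi_values)[g >= baseline_band[1] & g <= baseline_band[2]]
  if (length(x) < 2 || length(y) < 2) stop("band contains fewer than 2 grid points")
  if (sd(x) == 0 && sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  t.test(x, y)$p.value
}

#' @importFrom stats sd
NULL
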