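# Circular-dichroism post-processing: millidegree -> molar ellipticity
# conversion, high-tension reliability flagging, grouping of external
# secondary-structure fraction tables, and subtraction of terminal-block
# contributions from whole-construct fraction tables.

#' CD spectrum container
#'
#' @param wavelength wavelength grid, nm (strictly monotone).
#' @param signal CD signal values.
#' @param units `"mdeg"` (raw millidegrees) or `"molar_ellipticity"`
#'   (deg cm^2 dmol^-1).
#' @param mw average molecular weight of the construct, g/mol.
#' @param conc protein concentration, g/L.
#' @param path_length cuvette path length, cm.
#' @param ht optional high-tension channel, volts, same grid.
#' @return data.frame of class `cd_spectrum` with columns `wavelength`,
#'   `signal` (and `ht` when given); conversion metadata in attributes.
#' @export
cd_spectrum <- function(wavelength, signal, units = c("mdeg",
                                                      "molar_ellipticity"),
                        mw = NULL, conc = NULL, path_length = NULL,
                        ht = NULL) {
  units <- match.arg(units)
  if (length(wavelength) != length(signal)) {
    stop("wavelength and signal lengths differ")
  }
  dw <- diff(wavelength)
  if (length(dw) && !(all(dw > 0) || all(dw < 0))) {
    stop("wavelength grid must be strictly monotone")
  }
  out <- data.frame(wavelength = wavelength, signal = signal)
  if (!is.null(ht)) {
    if (length(ht) != length(wavelength)) stop("ht length mismatch")
    out$ht <- ht
  }
  structure(out, units = units, mw = mw, conc = conc,
            path_length = path_length,
            class = c("cd_spectrum", "data.frame"))
}

#' Read a CD spectrum from a TSV file
#'
#' Two or three tab-separated columns: wavelength (nm), signal (mdeg), and
#' optionally the high-tension voltage (V). Lines starting with `#` are
#' skipped.
#'
#' @param path file path.
#' @param ... metadata passed to [cd_spectrum()] (`mw`, `conc`,
#'   `path_length`).
#' @return a `cd_spectrum`.
#' @export
read_cd_spectrum <- function(path, ...) {
  d <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#")
  cd_spectrum(d[[1]], d[[2]], units = "mdeg",
              ht = if (ncol(d) >= 3) d[[3]] else NULL, ...)
}

#' Convert millidegrees to molar ellipticity
#'
#' \eqn{[\theta](\lambda) = m(\lambda) \, M / (10 \, c \, l)} with m the CD
#' signal in millidegrees, M the average molecular weight (g/mol), c the
#' protein concentration (g/L) and l the path length (cm). The conversion is
#' linear and exactly invertible.
#'
#' @param spectrum a `cd_spectrum` in mdeg with `mw`, `conc` and
#'   `path_length` set (or supplied here).
#' @param mw,conc,path_length override/supply the conversion metadata.
#' @return a `cd_spectrum` in deg cm^2 dmol^-1.
#' @export
to_molar_ellipticity <- function(spectrum, mw = attr(spectrum, "mw"),
                                 conc = attr(spectrum, "conc"),
                                 path_length = attr(spectrum, "path_length")) {
  if (attr(spectrum, "units") != "mdeg") {
    stop("spectrum is not in millidegrees")
  }
  if (is.null(mw) || is.null(conc) || is.null(path_length)) {
    stop("mw, conc and path_length are all required for the conversion")
  }
  if (conc <= 0 || path_length <= 0) stop("conc and path_length must be > 0")
  theta <- spectrum$signal * mw / (10 * conc * path_length)
  cd_spectrum(spectrum$wavelength, theta, units = "molar_ellipticity",
              mw = mw, conc = conc, path_length = path_length,
              ht = spectrum$ht)
}

#' Invert a molar-ellipticity spectrum back to millidegrees
#'
#' @param spectrum a `cd_spectrum` in molar ellipticity with metadata set.
#' @return a `cd_spectrum` in mdeg.
#' @export
from_molar_ellipticity <- function(spectrum) {
  if (attr(spectrum, "units") != "molar_ellipticity") {
    stop("spectrum is not in molar ellipticity")
  }
  mw <- attr(spectrum, "mw"); conc <- attr(spectrum, "conc")
  l <- attr(spectrum, "path_length")
  m <- spectrum$signal * 10 * conc * l / mw
  cd_spectrum(spectrum$wavelength, m, units = "mdeg", mw = mw, conc = conc,
              path_length = l, ht = spectrum$ht)
}

#' Flag unreliable wavelengths from the high-tension channel
#'
#' Detector voltages above the threshold (default 1000 V) make the CD signal
#' unreliable; the returned mask marks those wavelengths.
#'
#' @param spectrum a `cd_spectrum` with an `ht` column.
#' @param threshold volts (default 1000).
#' @return logical vector, TRUE where the measurement is unreliable.
#' @export
flag_high_tension <- function(spectrum, threshold = 1000) {
  if (is.null(spectrum$ht)) {
    warning("no high-tension channel; all wavelengths treated as reliable")
    return(rep(FALSE, nrow(spectrum)))
  }
  spectrum$ht > threshold
}

#' Block composition of a fusion construct
#'
#' @param names block names in chain order (e.g. CBM, AQ12, CBM).
#' @param lengths residue counts per block.
#' @param fractions named list of per-block fraction vectors (each a named
#'   numeric vector summing to 1); blocks whose fractions are unknown (the
#'   subtraction target) may be `NULL`.
#' @return data.frame-backed list of class `block_composition`.
#' @export
block_composition <- function(names, lengths, fractions) {
  if (any(lengths <= 0)) stop("block lengths must be > 0")
  stopifnot(length(names) == length(lengths),
            length(fractions) == length(names))
  for (k in seq_along(fractions)) {
    f <- fractions[[k]]
    if (!is.null(f) && abs(sum(f) - 1) > 1e-6) {
      stop("fractions of block '", names[k], "' do not sum to 1")
    }
  }
  structure(list(names = names, lengths = lengths, fractions = fractions),
            class = "block_composition")
}

#' Subtract terminal-block contributions from a whole-construct table
#'
#' With length weights \eqn{w_b}, solves
#' \eqn{f_{target} = (f_{total} - \sum_{b \ne target} w_b f_b) / w_{target}}.
#' Small negative components (> -0.05), which arise routinely when
#' subtracting noisy fraction estimates, are clipped to zero and the result
#' renormalized; larger negatives are an error.
#'
#' @param total named numeric vector of whole-construct fractions (sums
#'   to 1).
#' @param blocks a [block_composition()]; every block except `target_block`
#'   must carry fractions.
#' @param target_block name of the block whose fractions to recover.
#' @param total_length expected whole-construct residue count; when given,
#'   checked against the sum of block lengths.
#' @return named numeric vector of the target block's fractions.
#' @export
subtract_block_contribution <- function(total, blocks, target_block,
                                        total_length = NULL) {
  ti <- which(blocks$names == target_block)
  if (length(ti) != 1L) {
    stop("target block '", target_block, "' must appear exactly once; found ",
         length(ti))
  }
  if (!is.null(total_length) && sum(blocks$lengths) != total_length) {
    stop("block lengths sum to ", sum(blocks$lengths), ", expected ",
         total_length)
  }
  if (abs(sum(total) - 1) > 1e-6) stop("total fractions must sum to 1")
  keys <- names(total)
  w <- blocks$lengths / sum(blocks$lengths)
  acc <- total
  for (b in seq_along(blocks$names)) {
    if (b == ti) next
    fb <- blocks$fractions[[b]]
    if (is.null(fb)) stop("block '", blocks$names[b], "' has no fractions")
    if (!all(keys %in% names(fb))) {
      stop("block '", blocks$names[b], "' lacks keys: ",
           paste(setdiff(keys, names(fb)), collapse = ", "))
    }
    acc <- acc - w[b] * fb[keys]
  }
  f <- acc / w[ti]
  if (any(f < -0.05)) {
    stop("infeasible subtraction: component(s) ",
         paste(keys[f < -0.05], collapse = ", "), " below -0.05")
  }
  f <- pmax(f, 0)
  f / sum(f)
}

#' Group raw CD fractions into ordered / turns / other
#'
#' Ordered collects helices and beta-sheets; turns stay turns; other collects
#' coil (and bend when present). The total is preserved exactly.
#'
#' @param raw named numeric vector with keys among `helix`, `beta_sheet`
#'   (or `sheet`), `turn`, `coil`, `bend`.
#' @return named numeric vector with keys `ordered`, `turns`, `other`.
#' @export
group_cd_fractions <- function(raw) {
  key_map <- c(helix = "ordered", beta_sheet = "ordered", sheet = "ordered",
               turn = "turns", coil = "other", bend = "other")
  nm <- tolower(names(raw))
  nm <- gsub("[^a-z]+", "_", nm)
  nm <- sub("^_|_$", "", nm)
  nm[nm %in% c("b_sheet", "beta", "strand")] <- "beta_sheet"
  unknown <- setdiff(nm, names(key_map))
  if (length(unknown)) {
    stop("unknown structure key(s): ", paste(unknown, collapse = ", "))
  }
  out <- c(ordered = 0, turns = 0, other = 0)
  for (k in seq_along(raw)) out[key_map[nm[k]]] <- out[key_map[nm[k]]] + raw[k]
  out
}

#' Read a fraction table from TSV
#'
#' Two tab-separated columns: structure name and fraction. The tables written
#' by external spectral-decomposition tools (e.g. BeStSel exports) are
#' consumed in this form.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_fraction_table <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  structure(as.numeric(d[[2]]), names = as.character(d[[1]]))
}
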