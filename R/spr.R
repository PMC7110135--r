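#' SPR sensorgram container
#'
#' A raw resonance-unit trace from one flow cell, with the injection
#' metadata needed to reference and normalize it.
#'
#' @param time_s Strictly increasing time vector, s.
#' @param response_ru Response in resonance units (RU), same length.
#' @param substrate_name Immobilised substrate identifier.
#' @param concentration_um Injected analyte (RAD51 monomer) concentration, uM.
#' @param ligand_level_ru Amount of immobilised DNA ligand L, RU (> 0 for
#'   experimental cells; may be 0 for control cells).
#' @param t_association_s,t_dissociation_s Phase durations, s (association
#'   starts at t = 0).
#' @param flow_cell Optional flow-cell identifier.
#' @return A `sensorgram`: data frame (`time_s`, `response_ru`) with
#'   metadata attributes.
#' @export
sensorgram <- function(time_s, response_ru,
                       substrate_name = NA_character_,
                       concentration_um = NA_real_,
                       ligand_level_ru = NA_real_,
                       t_association_s = NA_real_,
                       t_dissociation_s = NA_real_,
                       flow_cell = NA_character_) {
  stopifnot(is.numeric(time_s), is.numeric(response_ru),
            length(time_s) == length(response_ru))
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    stop("'time_s' must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(time_s = as.numeric(time_s),
               response_ru = as.numeric(response_ru)),
    substrate_name = substrate_name,
    concentration_um = as.numeric(concentration_um),
    ligand_level_ru = as.numeric(ligand_level_ru),
    t_association_s = as.numeric(t_association_s),
    t_dissociation_s = as.numeric(t_dissociation_s),
    flow_cell = flow_cell,
    class = c("sensorgram", "data.frame")
  )
}

#' Normalized SPR curve: mean RAD51 per DNA molecule
#'
#' @param time_s Time vector, s.
#' @param n_bound Mean number of RAD51 protomers per DNA molecule.
#' @param substrate_name,concentration_um Metadata.
#' @param phase Optional per-point phase labels.
#' @return A `normalized_curve` data frame with metadata attributes.
#' @export
normalized_curve <- function(time_s, n_bound,
                             substrate_name = NA_character_,
                             concentration_um = NA_real_,
                             phase = NULL) {
  stopifnot(length(time_s) == length(n_bound))
  structure(
    data.frame(time_s = as.numeric(time_s), n_bound = as.numeric(n_bound)),
    substrate_name = substrate_name,
    concentration_um = as.numeric(concentration_um),
    phase = phase,
    class = c("normalized_curve", "data.frame")
  )
}

sensorgram_meta <- function(sg) {
  list(substrate_name = attr(sg, "substrate_name"),
       concentration_um = attr(sg, "concentration_um"),
       ligand_level_ru = attr(sg, "ligand_level_ru"),
       t_association_s = attr(sg, "t_association_s"),
       t_dissociation_s = attr(sg, "t_dissociation_s"),
       flow_cell = attr(sg, "flow_cell"))
}

resample_to <- function(time_s, response, target_time) {
  if (min(target_time) < min(time_s) - 1e-9 ||
      max(target_time) > max(time_s) + 1e-9) {
    stop("traces do not overlap on a common time range", call. = FALSE)
  }
  stats::approx(time_s, response, xout = target_time, rule = 2)$y
}

#' Double-reference an SPR sensorgram
#'
#' Subtracts the negative-control flow-cell trace and, if supplied, the
#' control-vs-experimental drift trace recorded during the final buffer
#' priming injection, then zeroes the result on the 5 s window before the
#' injection start (t = 0). Control and drift traces are linearly
#' interpolated onto the experimental time base when the grids differ.
#'
#' @param experimental,control `sensorgram` objects on overlapping time
#'   ranges; `control` is the reference flow cell.
#' @param drift Optional `sensorgram` of the residual baseline drift.
#' @return A referenced `sensorgram` on the experimental time base.
#' @export
double_reference <- function(experimental, control, drift = NULL) {
  stopifnot(inherits(experimental, "sensorgram"),
            inherits(control, "sensorgram"))
  tt <- experimental$time_s
  resp <- experimental$response_ru -
    resample_to(control$time_s, control$response_ru, tt)
  if (!is.null(drift)) {
    stopifnot(inherits(drift, "sensorgram"))
    resp <- resp - resample_to(drift$time_s, drift$response_ru, tt)
  }
  pre <- tt < 0 & tt >= -5
  if (any(pre)) resp <- resp - mean(resp[pre])
  meta <- sensorgram_meta(experimental)
  sensorgram(tt, resp,
             substrate_name = meta$substrate_name,
             concentration_um = meta$concentration_um,
             ligand_level_ru = meta$ligand_level_ru,
             t_association_s = meta$t_association_s,
             t_dissociation_s = meta$t_dissociation_s,
             flow_cell = meta$flow_cell)
}

#' Normalize an SPR signal to mean RAD51 molecules per DNA
#'
#' Applies `N = S / (L * (M_RAD51 / M_DNA))`: the RU signal divided by the
#' immobilised ligand level scaled by the RAD51/DNA mass ratio. RU reports
#' mass at the surface, so the ratio of protein RU to DNA RU times the mass
#' ratio counts molecules.
#'
#' @param sg A referenced `sensorgram` (or any RU series wrapped in one).
#' @param ligand_level_ru Immobilised DNA level L in RU; defaults to the
#'   sensorgram's metadata.
#' @param m_dna_kda Molar mass of the immobilised DNA, kDa; defaults to the
#'   catalogue mass of the sensorgram's substrate.
#' @param m_rad51_kda Molar mass of RAD51, kDa (default 37).
#' @return A `normalized_curve`.
#' @examples
#' sg <- sensorgram(0:3, c(0, 10, 20, 40), ligand_level_ru = 10)
#' normalize_sensorgram(sg, m_dna_kda = 18.5) # mass ratio 2 -> N = S / 20
#' @export
normalize_sensorgram <- function(sg, ligand_level_ru = NULL,
                                 m_dna_kda = NULL, m_rad51_kda = 37) {
  stopifnot(inherits(sg, "sensorgram"))
  L <- ligand_level_ru %||% attr(sg, "ligand_level_ru")
  if (is.null(m_dna_kda)) {
    nm <- attr(sg, "substrate_name")
    if (is.na(nm)) {
      stop("supply 'm_dna_kda' or a sensorgram with a substrate name",
           call. = FALSE)
    }
    m_dna_kda <- get_substrate(nm)$mass_kda
  }
  if (is.na(L) || L <= 0) stop("'ligand_level_ru' must be > 0", call. = FALSE)
  if (m_dna_kda <= 0 || m_rad51_kda <= 0) {
    stop("masses must be positive", call. = FALSE)
  }
  normalized_curve(sg$time_s, sg$response_ru / (L * (m_rad51_kda / m_dna_kda)),
                   substrate_name = attr(sg, "substrate_name"),
                   concentration_um = attr(sg, "concentration_um"))
}

#' Convert a normalized curve back to raw RU
#'
#' Inverse of [normalize_sensorgram()]: `S = N * L * (M_RAD51 / M_DNA)`.
#'
#' @param curve A `normalized_curve`.
#' @param ligand_level_ru Immobilised DNA level L, RU.
#' @param m_dna_kda DNA molar mass, kDa.
#' @param m_rad51_kda RAD51 molar mass, kDa.
#' @inheritParams sensorgram
#' @return A `sensorgram`.
#' @export
denormalize_curve <- function(curve, ligand_level_ru, m_dna_kda,
                              m_rad51_kda = 37,
                              t_association_s = NA_real_,
                              t_dissociation_s = NA_real_) {
  stopifnot(inherits(curve, "normalized_curve"),
            ligand_level_ru > 0, m_dna_kda > 0, m_rad51_kda > 0)
  sensorgram(curve$time_s,
             curve$n_bound * ligand_level_ru * (m_rad51_kda / m_dna_kda),
             substrate_name = attr(curve, "substrate_name"),
             concentration_um = attr(curve, "concentration_um"),
             ligand_level_ru = ligand_level_ru,
             t_association_s = t_association_s,
             t_dissociation_s = t_dissociation_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write sensorgrams in the package CSV dialect
#'
#' Plain CSV with columns `time_s,response_ru`; metadata (substrate,
#' concentration, ligand level, phase durations, flow cell) is carried as
#' YAML in `#`-prefixed header lines, so one file is self-describing.
#'
#' @param sg A `sensorgram`.
#' @param path File path.
#' @return `read_sensorgram()` returns a `sensorgram`; `write_sensorgram()`
#'   returns `path` invisibly.
#' @export
write_sensorgram <- function(sg, path) {
  stopifnot(inherits(sg, "sensorgram"))
  meta <- sensorgram_meta(sg)
  meta <- meta[!vapply(meta, function(x) is.null(x) ||
                         (length(x) == 1L && is.na(x)), logical(1))]
  hdr <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,response_ru", con)
  utils::write.table(data.frame(sg$time_s, sg$response_ru), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  if (any(is_meta)) {
    meta <- yaml::yaml.load(paste(sub("^#\\s?", "", lines[is_meta]),
                                  collapse = "\n"))
  }
  tab <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  if (!all(c("time_s", "response_ru") %in% names(tab))) {
    stop("sensorgram file must have columns time_s,response_ru",
         call. = FALSE)
  }
  sensorgram(tab$time_s, tab$response_ru,
             substrate_name = meta$substrate_name %||% NA_character_,
             concentration_um = meta$concentration_um %||% NA_real_,
             ligand_level_ru = meta$ligand_level_ru %||% NA_real_,
             t_association_s = meta$t_association_s %||% NA_real_,
             t_dissociation_s = meta$t_dissociation_s %||% NA_real_,
             flow_cell = meta$flow_cell %||% NA_character_)
}
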