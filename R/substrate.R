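#' DNA substrate descriptions
#'
#' A `dna_substrate` describes one immobilised oligonucleotide: its
#' strandedness, length (nucleotides for single strands, base pairs for
#' duplexes), molar mass of the full immobilised species in kDa, the maximum
#' number of RAD51 protomers it can accommodate (one protomer occludes three
#' nucleotides), and, where measured, its Kuhn and persistence lengths.
#'
#' @param name Substrate identifier, e.g. `"dN-50"`.
#' @param strandedness `"single"` or `"double"`.
#' @param length_nt Length in nucleotides (base pairs for duplexes).
#' @param mass_kda Molar mass of the immobilised species in kDa.
#' @param kuhn_length_nm Optional Kuhn length in nm (`NA` if unmeasured).
#'
#' @return An object of class `dna_substrate`.
#' @examples
#' dna_substrate("dN-17", "single", 17, 5.795)
#' @export
dna_substrate <- function(name, strandedness = c("single", "double"),
                          length_nt, mass_kda, kuhn_length_nm = NA_real_) {
  strandedness <- match.arg(strandedness)
  if (!is.numeric(length_nt) || length(length_nt) != 1L ||
      is.na(length_nt) || length_nt < 1 || length_nt != floor(length_nt)) {
    stop("'length_nt' must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(mass_kda) || length(mass_kda) != 1L ||
      is.na(mass_kda) || mass_kda <= 0) {
    stop("'mass_kda' must be a single positive number", call. = FALSE)
  }
  if (!is.na(kuhn_length_nm) && kuhn_length_nm < 0) {
    stop("'kuhn_length_nm' must be non-negative", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name),
      strandedness = strandedness,
      length_nt = as.integer(length_nt),
      mass_kda = as.numeric(mass_kda),
      capacity = rad51_capacity(length_nt),
      kuhn_length_nm = as.numeric(kuhn_length_nm),
      persistence_length_nm = if (is.na(kuhn_length_nm)) NA_real_ else
        kuhn_to_persistence(kuhn_length_nm)
    ),
    class = "dna_substrate"
  )
}

#' @export
print.dna_substrate <- function(x, ...) {
  cat(sprintf("<dna_substrate> %s (%s-stranded, %d nt, %.3f kDa)\n",
              x$name, x$strandedness, x$length_nt, x$mass_kda))
  cat(sprintf("  RAD51 capacity: %d protomers\n", x$capacity))
  if (!is.na(x$kuhn_length_nm)) {
    cat(sprintf("  Kuhn length: %.4f nm, persistence length: %.4f nm\n",
                x$kuhn_length_nm, x$persistence_length_nm))
  }
  invisible(x)
}

#' Maximum number of RAD51 protomers a DNA substrate accommodates
#'
#' One RAD51 protomer engages three nucleotides of DNA, so a substrate of
#' `length_nt` nucleotides carries at most `floor(length_nt / 3)` protomers;
#' a partial footprint binds nothing.
#'
#' @param length_nt Substrate length in nucleotides (base pairs for duplexes).
#' @return Integer protomer capacity.
#' @examples
#' rad51_capacity(50) # 16
#' rad51_capacity(17) # 5
#' @export
rad51_capacity <- function(length_nt) {
  if (!is.numeric(length_nt) || anyNA(length_nt) ||
      any(length_nt < 0) || any(length_nt != floor(length_nt))) {
    stop("'length_nt' must be non-negative integer(s)", call. = FALSE)
  }
  as.integer(length_nt %/% 3)
}

#' Convert a Kuhn length to a persistence length
#'
#' For a worm-like chain the persistence length is half the Kuhn length.
#'
#' @param kuhn_length_nm Kuhn length in nm (non-negative).
#' @return Persistence length in nm.
#' @examples
#' kuhn_to_persistence(2.6702) # 1.3351
#' @export
kuhn_to_persistence <- function(kuhn_length_nm) {
  if (!is.numeric(kuhn_length_nm) || anyNA(kuhn_length_nm) ||
      any(kuhn_length_nm < 0)) {
    stop("'kuhn_length_nm' must be non-negative", call. = FALSE)
  }
  kuhn_length_nm / 2
}

#' The catalogue of DNA substrates used in the RAD51 SPR study design
#'
#' Twelve biotinylated oligonucleotides: mixed-base single strands of 5, 8,
#' 11, 14, 17 and 50 nt; hairpin duplexes of 5, 8, 11 and 50 bp; and the
#' homopolymeric dT-50 and dA-50 50-mers. Masses are those of the full
#' immobilised species (duplex masses include both strands and linkers).
#' The four 50-mers carry SAXS-derived Kuhn lengths.
#'
#' @param path Optional path to a user catalogue CSV with columns
#'   `name,strandedness,length_nt,mass_kda,kuhn_length_nm`.
#' @return A named list of [dna_substrate] objects.
#' @examples
#' names(substrate_catalog())
#' substrate_catalog()[["dN-50"]]
#' @export
substrate_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "substrates.csv", package = "rad51kin")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "strandedness", "length_nt", "mass_kda", "kuhn_length_nm")
  if (!all(need %in% names(tab))) {
    stop("substrate table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    dna_substrate(tab$name[i], tab$strandedness[i], tab$length_nt[i],
                  tab$mass_kda[i], tab$kuhn_length_nm[i])
  })
  names(out) <- tab$name
  out
}

#' Look up one substrate from the catalogue by name
#'
#' @param name Substrate name, e.g. `"dN-50p"`.
#' @param catalog A catalogue as returned by [substrate_catalog()].
#' @return A [dna_substrate].
#' @export
get_substrate <- function(name, catalog = substrate_catalog()) {
  if (!name %in% names(catalog)) {
    stop("substrate '", name, "' is not in the catalogue; available: ",
         paste(names(catalog), collapse = ", "), call. = FALSE)
  }
  catalog[[name]]
}
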