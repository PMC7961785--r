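# Ektacytometry elongation index and red-cell indices.

#' Elongation index
#'
#' EI = (L - W) / (L + W) from the length and width of the laser diffraction
#' pattern of red cells under shear. Physically W <= L is expected; W > L
#' yields a negative EI with a warning rather than an error, since the
#' diffraction-pattern axes can swap at low shear.
#'
#' @param L,W positive diffraction-pattern length and width (same units).
#' @return EI in (-1, 1); vectorized.
#' @export
elongation_index <- function(L, W) {
  if (any(L <= 0) || any(W <= 0)) abort("L and W must be positive")
  if (any(W > L))
    warning("W > L: negative elongation index (axes may be swapped)",
            call. = FALSE)
  (L - W) / (L + W)
}

#' Deformability record
#'
#' A shear sweep for one sample: shear stresses (Pa, strictly increasing
#' within 0.5-20 Pa) with L, W and EI per stop. EI is recomputed from L and W
#' when both are present and cross-checked against any supplied EI column.
#'
#' @param sample_id sample identifier.
#' @param shear_Pa strictly increasing shear stresses in Pa.
#' @param L,W optional diffraction-pattern dimensions.
#' @param EI optional elongation indices (required if L/W absent).
#' @return a `deformability_record`.
#' @export
deformability_record <- function(sample_id, shear_Pa, L = NULL, W = NULL,
                                 EI = NULL) {
  shear_Pa <- as.double(shear_Pa)
  if (!length(shear_Pa)) abort("empty shear sweep")
  if (any(diff(shear_Pa) <= 0)) abort("shear stresses must be strictly increasing")
  if (min(shear_Pa) < 0.5 - 1e-9 || max(shear_Pa) > 20 + 1e-9)
    abort("shear stresses must lie within [0.5, 20] Pa")
  if (!is.null(L) && !is.null(W)) {
    ei <- elongation_index(L, W)
    if (!is.null(EI) && max(abs(ei - EI)) > 1e-6)
      warning("supplied EI disagrees with (L-W)/(L+W); recomputed values used",
              call. = FALSE)
    EI <- ei
  }
  if (is.null(EI)) abort("need either L and W, or EI")
  if (any(abs(EI) >= 1)) abort("EI must lie in (-1, 1)")
  structure(list(sample_id = as.character(sample_id), shear_Pa = shear_Pa,
                 L = L, W = W, EI = as.double(EI)),
            class = "deformability_record")
}

#' Maximum elongation index of a shear sweep
#'
#' EImax is read at the highest shear stress of the sweep (nominally 20 Pa);
#' sweeps whose top shear is below 19.5 Pa are rejected as incomplete
#' (tolerance accommodates instrument grids ending at 19.8-20.0 Pa).
#'
#' @param rec a [deformability_record()].
#' @return EI at the largest shear stress.
#' @export
ei_max <- function(rec) {
  stopifnot(inherits(rec, "deformability_record"))
  top <- length(rec$shear_Pa)
  if (rec$shear_Pa[top] < 19.5)
    abort("incomplete shear sweep: top shear ", rec$shear_Pa[top],
          " Pa < 19.5 Pa")
  rec$EI[top]
}

#' Read deformability records from a delimited table
#'
#' Expected columns: `sample_id`, `shear_Pa`, and either `L` and `W` or `EI`.
#'
#' @param path CSV path.
#' @return list of [deformability_record()]s.
#' @export
read_deformability <- function(path) {
  df <- read_table_file(path)
  if (!all(c("sample_id", "shear_Pa") %in% names(df)))
    abort("deformability table needs sample_id and shear_Pa columns")
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$shear_Pa), ]
    deformability_record(d$sample_id[1], d$shear_Pa,
                         L = if ("L" %in% names(d)) d$L,
                         W = if ("W" %in% names(d)) d$W,
                         EI = if ("EI" %in% names(d)) d$EI)
  })
}

#' Derive red-cell indices from a complete blood count
#'
#' Standard hematology identities: MCV = 10 HCT / RBC (fL),
#' MCH = 10 HGB / RBC (pg), MCHC = 100 HGB / HCT (g/dL).
#'
#' @param HGB hemoglobin, g/dL.
#' @param HCT hematocrit, percent.
#' @param RBC red-cell count, 10\eqn{^6}/\eqn{\mu}L.
#' @param RDW optional red-cell distribution width, percent.
#' @return a `cbc_record` list with inputs and derived MCV, MCH, MCHC.
#' @export
derive_cbc <- function(HGB, HCT, RBC, RDW = NA_real_) {
  if (any(c(HGB, HCT, RBC) <= 0) || anyNA(c(HGB, HCT, RBC)))
    abort("HGB, HCT and RBC must be positive")
  structure(list(HGB = HGB, HCT = HCT, RBC = RBC, RDW = RDW,
                 MCV = 10 * HCT / RBC, MCH = 10 * HGB / RBC,
                 MCHC = 100 * HGB / HCT),
            class = "cbc_record")
}
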