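# Built-in nine-property registry. Rows are per-residue scales in the
# alphabetical single-letter residue order of amino_acids(). Sources:
#   hydrophobicity      — consensus hydrophobicity scale as tabulated for
#                         type-1 pseudo amino acid composition descriptors
#   hydrophilicity      — Hopp & Woods (1981) PNAS 78:3824
#   side_chain_mass     — side-chain molecular mass (Da, glycine = 1)
#   pK_COOH             — pK of the alpha-carboxyl group
#   pK_NH3              — pK of the alpha-amino group
#   isoelectric_point   — pI of the free amino acid at 25 C
#   bulkiness           — Zimmerman, Eliezer & Simha (1968) J Theor Biol 21:170
#                         (steric bulk; proxy for side-chain rigidity)
#   flexibility         — Bhaskaran & Ponnuswamy (1988) average flexibility
#   relative_mutability — Dayhoff, Schwartz & Orcutt (1978) (inverse sense of
#                         residue irreplaceability)
.default9_raw <- function() {
  m <- rbind(
    hydrophobicity = c(0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38,
                       -1.50, 1.06, 0.64, -0.78, 0.12, -0.85, -2.53, -0.18,
                       -0.05, 1.08, 0.81, 0.26),
    hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0,
                       -1.8, -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5,
                       -3.4, -2.3),
    side_chain_mass = c(15, 47, 59, 73, 91, 1, 82, 57, 73, 57, 75, 58, 42,
                        72, 101, 31, 45, 43, 130, 107),
    pK_COOH = c(2.35, 1.71, 1.88, 2.19, 2.58, 2.34, 1.78, 2.32, 2.20, 2.36,
                2.28, 2.18, 1.99, 2.17, 2.17, 2.21, 2.15, 2.29, 2.38, 2.20),
    pK_NH3 = c(9.87, 10.78, 9.60, 9.67, 9.24, 9.60, 8.97, 9.76, 8.90, 9.60,
               9.21, 9.09, 10.60, 9.13, 9.04, 9.15, 9.12, 9.74, 9.39, 9.11),
    isoelectric_point = c(6.11, 5.02, 2.98, 3.08, 5.91, 6.06, 7.64, 6.04,
                          9.47, 6.04, 5.74, 5.41, 6.30, 5.65, 10.76, 5.68,
                          5.60, 6.02, 5.88, 5.63),
    bulkiness = c(11.50, 13.46, 11.68, 13.57, 19.80, 3.40, 13.69, 21.40,
                  15.71, 21.40, 16.25, 12.82, 17.43, 14.45, 14.28, 9.47,
                  15.77, 21.57, 21.67, 18.03),
    flexibility = c(0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462,
                    0.466, 0.365, 0.295, 0.463, 0.509, 0.493, 0.529, 0.507,
                    0.444, 0.386, 0.305, 0.420),
    relative_mutability = c(100, 20, 106, 102, 41, 49, 66, 96, 56, 40, 94,
                            134, 56, 93, 65, 120, 97, 74, 18, 41)
  )
  colnames(m) <- amino_acids()
  m
}

#' Standardize a per-residue property matrix
#'
#' Applies the standard conversion used for sequence-order correlation
#' features: each property row is centred on its mean over the 20 residues
#' and divided by its population standard deviation (denominator 20). The
#' output rows have mean 0 and population SD 1, and the conversion is
#' idempotent: applying it to already-standardized rows returns them
#' unchanged.
#'
#' @param raw Numeric matrix, n properties x 20 residues, columns in the
#'   order of [amino_acids()].
#' @return Numeric matrix of the same shape with standardized rows.
#' @export
standardize_properties <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20) {
    stop("property matrix must have 20 residue columns, got ", ncol(raw))
  }
  centered <- raw - rowMeans(raw)
  pop_sd <- sqrt(rowSums(centered^2) / 20)
  zero <- pop_sd < 1e-12
  if (any(zero)) {
    nm <- rownames(raw)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero spread (constant values) in property: ",
         paste(nm, collapse = ", "))
  }
  centered / pop_sd
}

#' Build a property table
#'
#' @param raw Numeric matrix n x 20 of raw per-residue property values,
#'   rows named by property, columns in the order of [amino_acids()].
#' @return An object of class `property_table` with elements
#'   `property_names`, `raw` and `standardized`.
#' @export
property_table <- function(raw) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw))) {
    rownames(raw) <- paste0("property", seq_len(nrow(raw)))
  }
  if (anyDuplicated(rownames(raw))) {
    stop("duplicate property name: ",
         rownames(raw)[duplicated(rownames(raw))][1])
  }
  if (!is.numeric(raw) || anyNA(raw)) {
    stop("property table contains non-numeric or missing entries")
  }
  colnames(raw) <- amino_acids()
  structure(
    list(property_names = rownames(raw), raw = raw,
         standardized = standardize_properties(raw)),
    class = "property_table"
  )
}

#' @export
print.property_table <- function(x, ...) {
  cat("Property table:", length(x$property_names), "per-residue scales\n")
  cat(paste(" -", x$property_names, collapse = "\n"), "\n")
  invisible(x)
}

#' Number of properties in a table
#' @param table A [property_table()].
#' @return Integer count of property rows.
#' @export
n_properties <- function(table) length(table$property_names)

#' Load a property table from a file or the built-in registry
#'
#' The file format is tab-separated: a header line `property` followed by
#' the 20 residue letters in alphabetical order, then one line per property
#' (name, 20 numeric values). The built-in name `"default9"` loads the
#' nine-scale registry shipped with the package (hydrophobicity,
#' hydrophilicity, side-chain mass, pK of the alpha-COOH and alpha-NH3+
#' groups, isoelectric point, bulkiness, flexibility, relative mutability).
#'
#' @param source Path to a TSV file, or a registry name (`"default9"`).
#' @return A [property_table()].
#' @export
load_property_table <- function(source = "default9") {
  if (identical(source, "default9")) {
    return(property_table(.default9_raw()))
  }
  if (!file.exists(source)) {
    stop("property table not found: ", source, " (not a file or registry name)")
  }
  df <- utils::read.delim(source, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(amino_acids() %in% colnames(df))) {
    missing <- setdiff(amino_acids(), colnames(df))
    stop("property file is missing residue column(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- df[, amino_acids(), drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop("property file has non-numeric entries")
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(df[[1]])
  property_table(m)
}

#' Write a property table's raw values to a TSV file
#'
#' @param table A [property_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_property_table <- function(table, path) {
  df <- data.frame(property = table$property_names, table$raw,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
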