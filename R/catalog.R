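#' The default parameter catalog
#'
#' Reconstructs the catalog of biologically motivated parameters computed on
#' every (ppri-miRNA, pre-miRNA, miRNA) triple, organised in five categories:
#' Descriptive (identifier, sequence and structure strings), Size (lengths
#' and paired-base counts), Stability (folding free energies), Sequence
#' (nucleotide/GC contents and the miRNA first base) and Structure (unpaired
#' bases and rates, GU wobbles, internal-loop statistics and the 3' overhang
#' at the pre-miRNA base).
#'
#' `svm_eligible` marks parameters usable as SVM input: descriptive and
#' categorical parameters are excluded, as is every ppri-miRNA-scoped
#' parameter, because random-start decoys share the positive example's
#' ppri-miRNA and those values cannot discriminate. The categorical miRNA
#' first base is one-hot encoded into four eligible indicator parameters.
#'
#' The catalog is configuration-driven: alternative reconstructions can be
#' written/loaded with [write_catalog()] / [read_catalog()] and are drop-in.
#'
#' @return data.frame with columns `name`, `category`, `scope`,
#'   `value_kind`, `svm_eligible`; attribute `version`.
#' @export
default_catalog <- function() {
  rows <- list()
  add <- function(name, category, scope, kind) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, category = category, scope = scope, value_kind = kind,
      stringsAsFactors = FALSE)
  }

  add("id", "descriptive", "pprimirna", "text")
  add("mi_sequence", "descriptive", "mirna", "text")
  add("pre_sequence", "descriptive", "premirna", "text")
  add("ppri_sequence", "descriptive", "pprimirna", "text")
  add("ppri_structure", "descriptive", "pprimirna", "text")

  add("mi_length", "size", "mirna", "integer")
  add("pre_length", "size", "premirna", "integer")
  add("ppri_length", "size", "pprimirna", "integer")
  add("basalsegment_length", "size", "basal_segment", "integer")
  add("lowerstem_length", "size", "lower_stem", "integer")
  add("upperstem_length", "size", "upper_stem", "integer")
  add("topstem_length", "size", "top_stem", "integer")
  add("terminalloop_length", "size", "terminal_loop", "integer")
  add("mi_pairs", "size", "mirna", "integer")
  add("pre_pairs", "size", "premirna", "integer")
  add("ppri_pairs", "size", "pprimirna", "integer")
  add("lowerstem_pairs", "size", "lower_stem", "integer")
  add("upperstem_pairs", "size", "upper_stem", "integer")
  add("topstem_pairs", "size", "top_stem", "integer")

  add("pre_mfe", "stability", "premirna", "real")
  add("ppri_mfe", "stability", "pprimirna", "real")

  for (sc in c("mi", "pre", "ppri")) {
    scope <- c(mi = "mirna", pre = "premirna", ppri = "pprimirna")[[sc]]
    for (b in c("a", "c", "g", "u", "gc"))
      add(paste0(sc, "_", b, "_content"), "sequence", scope, "real")
  }
  add("mi_firstbase", "sequence", "mirna", "categorical")
  for (b in c("a", "c", "g", "u"))
    add(paste0("mi_firstbase_", b), "sequence", "mirna", "integer")

  struct_scopes <- c(mi = "mirna", pre = "premirna", ppri = "pprimirna",
                     lowerstem = "lower_stem", upperstem = "upper_stem",
                     topstem = "top_stem")
  for (sc in names(struct_scopes)) {
    add(paste0(sc, "_unpaired_bases"), "structure", struct_scopes[[sc]], "integer")
    add(paste0(sc, "_unpaired_rate"), "structure", struct_scopes[[sc]], "real")
    add(paste0(sc, "_gu_wobbles"), "structure", struct_scopes[[sc]], "integer")
    add(paste0(sc, "_largest_internal_loop"), "structure", struct_scopes[[sc]], "integer")
    add(paste0(sc, "_n_internal_loops"), "structure", struct_scopes[[sc]], "integer")
  }
  add("overhang_3p", "structure", "lower_stem", "integer")

  cat_df <- do.call(rbind, rows)
  cat_df$svm_eligible <- !(cat_df$value_kind %in% c("text", "categorical")) &
    cat_df$scope != "pprimirna"
  attr(cat_df, "version") <- "mircand-catalog-1"
  cat_df
}

#' Write / read a parameter catalog as YAML
#' @param catalog catalog data.frame (see [default_catalog()]).
#' @param path YAML file.
#' @return `read_catalog()` returns the catalog data.frame.
#' @export
write_catalog <- function(catalog, path) {
  obj <- list(version = attr(catalog, "version") %||% "custom",
              parameters = lapply(seq_len(nrow(catalog)), function(i)
                as.list(catalog[i, , drop = FALSE])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  obj <- yaml::read_yaml(path)
  cat_df <- do.call(rbind, lapply(obj$parameters, function(p)
    data.frame(name = p$name, category = p$category, scope = p$scope,
               value_kind = p$value_kind, svm_eligible = p$svm_eligible,
               stringsAsFactors = FALSE)))
  attr(cat_df, "version") <- obj$version
  cat_df
}

#' Names of SVM-eligible parameters in a catalog
#' @param catalog catalog data.frame.
#' @return character vector.
#' @export
svm_eligible_params <- function(catalog = default_catalog()) {
  catalog$name[catalog$svm_eligible]
}
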