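# shared fixture loaders for the packaged reference tables
published_nfi <- function() {
  utils::read.delim(glycolink_extdata("lectin_nfi_vpa.tsv"),
                    stringsAsFactors = FALSE)
}

published_deggs <- function() {
  utils::read.delim(glycolink_extdata("degg_published.tsv"),
                    stringsAsFactors = FALSE)
}

packaged_gene_list <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- assemble_gene_list(build_gene_table())
    cache
  }
})

packaged_catalog <- function() {
  load_lectin_catalog(glycolink_extdata("lectin_catalog.tsv"))
}

packaged_actions <- function() {
  load_enzyme_actions(glycolink_extdata("enzyme_actions.tsv"))
}
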