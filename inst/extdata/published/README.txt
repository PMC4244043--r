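Drop-in location for the published data tables that the reproduction
entry points consume. The package ships no third-party data: these
files must be supplied by the user (the toolkit is otherwise exercised
on its own synthetic, ground-truthed generators, which are labelled
synthetic everywhere they stand in for published data).

Expected files and schemas (TSV, UTF-8, header row, '#' comments):

scaffold_alg_gene_pairs.tsv
    One row per ancestral-orthology gene pair anchoring a query
    scaffold to a reference ancestral linkage group (ALG).
    Columns: scaffold  family_id  alg_id  [gene_id]
    Consumed by reproduceSynteny(); other column layouts can be mapped
    with its `cols` argument.

gene_body_cpg_oe.tsv
    One row per gene with its gene-body CpG observed/expected ratio.
    Columns: gene  cpg_oe   (the value column name is configurable via
    reproduceCpg(column = ...))

scaffold_depths.tsv / samples.tsv
    Per-scaffold mean read depths per individual and the sample-sex
    table, in the schemas of readDepthTable() and readSampleSexes(),
    for re-running the sex-linkage classification on published depth
    data.
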