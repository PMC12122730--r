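# Container outputs: hasOutput to Data-typed members of generated containers
PREFIX neao_base: <http://purl.org/neao/base#>
PREFIX prov: <http://www.w3.org/ns/prov#>
PREFIX cap: <http://example.org/capture#>
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
INSERT { ?e neao_base:hasOutput ?m }
WHERE {
  ?e a neao_base:AnalysisStep .
  ?e prov:generated ?c .
  ?c prov:hadMember ?m .
  ?m a neao_base:Data .
}
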