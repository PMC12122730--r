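# Construct SoftwarePackage individuals from the captured package info
PREFIX neao_base: <http://purl.org/neao/base#>
PREFIX prov: <http://www.w3.org/ns/prov#>
PREFIX cap: <http://example.org/capture#>
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
INSERT {
  ?f neao_base:isImplementedInPackage ?p .
  ?p a neao_base:SoftwarePackage .
  ?p neao_base:packageName ?n .
  ?p neao_base:packageVersion ?v .
}
WHERE {
  ?e a neao_base:AnalysisStep .
  ?e cap:usedFunction ?f .
  ?f cap:inPackage ?p .
  ?p cap:packageName ?n .
  ?p cap:packageVersion ?v .
}
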