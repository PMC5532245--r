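# EU-25 2000-2012 per-class accounted areas and gross rill-and-sheet erosion rates
# implied by the published soil mass-balance account cells (back-solved inputs)
seea_code,area_ha,gross_rate_t_per_ha
2,110464899.2857,2.6700002979
3,10298530.0000,9.4692213355
4,46644861.5179,4.2105526870
5,47646651.1607,2.5749146899
6,158061822.1429,0.2270907011
8,17012480.7143,3.8668851477
10,3786063.8393,40.7581637686
11,117404.2857,20.9019541754
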