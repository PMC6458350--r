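species,pct_circle,is_rodent
Procavia capensis,11.74,FALSE
Vombatus ursinus,14.88,FALSE
Dendrohyrax arboreus,17.08,FALSE
Lagostomus maximus,20.36,TRUE
Oryctolagus cuniculus,21.48,FALSE
Cavia porcellus,24.54,TRUE
Laonastes aenigmamus,25.06,TRUE
Capromys pilorides,25.94,TRUE
Lepus europaeus,27.49,FALSE
Hydrochoerus hydrochaeris,28.21,TRUE
Aplodontia rufa,28.38,TRUE
Gerbillus watersi,29.10,TRUE
Dipus sagitta,31.83,TRUE
Acomys cahirinus,31.99,TRUE
Myocastor coypus,32.11,TRUE
Hystrix cristata,32.38,TRUE
Paralomys gerbillus,33.13,TRUE
Erethizon dorsatum,34.27,TRUE
Rattus norvegicus,35.06,TRUE
Graphiurus nagtglasii,35.31,TRUE
Castor canadensis,36.93,TRUE
Sciurus carolinensis,38.05,TRUE
Georychus capensis,38.17,TRUE
Pedetes capensis,38.40,TRUE
Cricetomys gambianius,38.73,TRUE
Thomomys umbrinus,38.86,TRUE
Cannomys badius,39.68,TRUE
Dasyprocta punctata,40.00,TRUE
Petaurista petaurista,40.42,TRUE
Ctenomys opimus,40.64,TRUE
Octodon degus,41.07,TRUE
Bathyergus suillus,45.04,TRUE
Daubentonia madagascariensis,50.75,FALSE
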