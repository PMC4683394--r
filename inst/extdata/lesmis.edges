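# Les Miserables character co-appearance network (77 nodes, 254 edges)
# Knuth, Stanford GraphBase
Babet Brujon
Babet Claquesous
Babet Montparnasse
Bahorel Bossuet
Bahorel Grantaire
Bahorel Joly
Bahorel MmeHucheloup
Bamatabois Brevet
Bamatabois Champmathieu
Bamatabois Chenildieu
Bamatabois Cochepaille
Bamatabois Judge
Blacheville Dahlia
Blacheville Fantine
Blacheville Favourite
Blacheville Zephine
Bossuet Grantaire
Bossuet Joly
Bossuet MmeHucheloup
Brevet Chenildieu
Brevet Cochepaille
Champmathieu Brevet
Champmathieu Chenildieu
Champmathieu Cochepaille
Chenildieu Cochepaille
Child1 Child2
Claquesous Brujon
Claquesous Montparnasse
Combeferre Bahorel
Combeferre Bossuet
Combeferre Courfeyrac
Combeferre Feuilly
Combeferre Grantaire
Combeferre Joly
Combeferre Prouvaire
Cosette Gillenormand
Cosette Javert
Cosette LtGillenormand
Cosette Marius
Cosette MlleGillenormand
Cosette Toussaint
Cosette Woman2
Courfeyrac Bahorel
Courfeyrac Bossuet
Courfeyrac Grantaire
Courfeyrac Joly
Courfeyrac MmeHucheloup
Dahlia Fantine
Dahlia Zephine
Enjolras Bahorel
Enjolras Bossuet
Enjolras Claquesous
Enjolras Combeferre
Enjolras Courfeyrac
Enjolras Feuilly
Enjolras Grantaire
Enjolras Joly
Enjolras MmeHucheloup
Enjolras Prouvaire
Eponine Anzelma
Eponine Babet
Eponine Brujon
Eponine Claquesous
Eponine Courfeyrac
Eponine Gueulemer
Eponine Mabeuf
Eponine Marius
Eponine Montparnasse
Fameuil Blacheville
Fameuil Dahlia
Fameuil Fantine
Fameuil Favourite
Fameuil Zephine
Fantine Bamatabois
Fantine Javert
Fantine MmeThenardier
Fantine Perpetue
Fantine Simplice
Fantine Thenardier
Fauchelevent Gribier
Fauchelevent MotherInnocent
Favourite Dahlia
Favourite Fantine
Favourite Zephine
Feuilly Bahorel
Feuilly Bossuet
Feuilly Courfeyrac
Feuilly Grantaire
Feuilly Joly
Gavroche Babet
Gavroche Bahorel
Gavroche Bossuet
Gavroche Brujon
Gavroche Child1
Gavroche Child2
Gavroche Combeferre
Gavroche Courfeyrac
Gavroche Enjolras
Gavroche Feuilly
Gavroche Grantaire
Gavroche Gueulemer
Gavroche Joly
Gavroche Mabeuf
Gavroche Marius
Gavroche MmeHucheloup
Gavroche Montparnasse
Gavroche Prouvaire
Gillenormand BaronessT
Gillenormand LtGillenormand
Gillenormand Magnon
Gillenormand Marius
Gillenormand MlleGillenormand
Grantaire MmeHucheloup
Gueulemer Babet
Gueulemer Brujon
Gueulemer Claquesous
Gueulemer Montparnasse
Javert Babet
Javert Bamatabois
Javert Claquesous
Javert Enjolras
Javert Fauchelevent
Javert Gavroche
Javert Gueulemer
Javert Montparnasse
Javert Simplice
Javert Toussaint
Javert Woman1
Javert Woman2
Joly Grantaire
Joly MmeHucheloup
Judge Brevet
Judge Champmathieu
Judge Chenildieu
Judge Cochepaille
Listolier Blacheville
Listolier Dahlia
Listolier Fameuil
Listolier Fantine
Listolier Favourite
Listolier Tholomyes
Listolier Zephine
LtGillenormand Marius
Mabeuf Bahorel
Mabeuf Bossuet
Mabeuf Combeferre
Mabeuf Courfeyrac
Mabeuf Enjolras
Mabeuf Feuilly
Mabeuf Joly
Mabeuf MotherPlutarch
Marguerite Fantine
Marius Bahorel
Marius BaronessT
Marius Bossuet
Marius Combeferre
Marius Courfeyrac
Marius Enjolras
Marius Feuilly
Marius Joly
Marius Mabeuf
MlleBaptistine MmeMagloire
MlleBaptistine Valjean
MlleGillenormand LtGillenormand
MlleGillenormand Marius
MlleGillenormand MlleVaubois
MlleGillenormand MmePontmercy
MmeBurgon Gavroche
MmeBurgon Jondrette
MmeMagloire Valjean
MmeThenardier Anzelma
MmeThenardier Babet
MmeThenardier Claquesous
MmeThenardier Cosette
MmeThenardier Eponine
MmeThenardier Gueulemer
MmeThenardier Javert
MmeThenardier Magnon
MmeThenardier Thenardier
Montparnasse Brujon
Myriel Champtercier
Myriel Count
Myriel CountessDeLo
Myriel Cravatte
Myriel Geborand
Myriel MlleBaptistine
Myriel MmeMagloire
Myriel OldMan
Myriel Valjean
Napoleon Myriel
Perpetue Simplice
Pontmercy Marius
Pontmercy MmePontmercy
Prouvaire Bahorel
Prouvaire Bossuet
Prouvaire Courfeyrac
Prouvaire Feuilly
Prouvaire Grantaire
Prouvaire Joly
Thenardier Anzelma
Thenardier Babet
Thenardier Boulatruelle
Thenardier Brujon
Thenardier Claquesous
Thenardier Cosette
Thenardier Eponine
Thenardier Gavroche
Thenardier Gueulemer
Thenardier Javert
Thenardier Marius
Thenardier Montparnasse
Thenardier Pontmercy
Tholomyes Blacheville
Tholomyes Cosette
Tholomyes Dahlia
Tholomyes Fameuil
Tholomyes Fantine
Tholomyes Favourite
Tholomyes Marius
Tholomyes Zephine
Valjean Babet
Valjean Bamatabois
Valjean Bossuet
Valjean Brevet
Valjean Champmathieu
Valjean Chenildieu
Valjean Claquesous
Valjean Cochepaille
Valjean Cosette
Valjean Enjolras
Valjean Fantine
Valjean Fauchelevent
Valjean Gavroche
Valjean Gervais
Valjean Gillenormand
Valjean Gueulemer
Valjean Isabeau
Valjean Javert
Valjean Judge
Valjean Labarre
Valjean Marguerite
Valjean Marius
Valjean MlleGillenormand
Valjean MmeDeR
Valjean MmeThenardier
Valjean Montparnasse
Valjean MotherInnocent
Valjean Scaufflaire
Valjean Simplice
Valjean Thenardier
Valjean Toussaint
Valjean Woman1
Valjean Woman2
Zephine Fantine
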